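#' 3D median denoising
#'
#' Median filter over a cubic `(2 radius + 1)^3` neighborhood with
#' reflecting edge handling; the standard acquisition-noise removal step
#' before surface segmentation.
#'
#' @param vol An [image_volume()].
#' @param radius Neighborhood radius in voxels (>= 1, smaller than the
#'   smallest volume dimension).
#' @return The filtered [image_volume()].
#' @export
denoise_median3d <- function(vol, radius = 1) {
  stopifnot(inherits(vol, "image_volume"))
  if (radius < 1) stop("radius must be >= 1")
  d <- dim(vol$data)
  if (radius >= min(d))
    stop("radius must be smaller than the smallest volume dimension (",
         min(d), ")")
  out <- cpp_median3d(as.numeric(vol$data), d[1], d[2], d[3],
                      as.integer(radius))
  vol$data <- array(as.integer(out), dim = d)
  vol
}

# multilevel Otsu thresholds on a vector of intensities: boundaries
# maximizing between-class variance on an n_bins histogram. Returns
# n_classes - 1 intensity cutoffs (class of v = findInterval(v, cuts))
# with the separability eta (between-class / total variance) attached;
# eta near 1 marks well-separated modes, while unimodal noise cannot
# exceed about 0.64 for any split.
otsu_thresholds <- function(values, n_classes = 3, n_bins = 256) {
  rng <- range(values)
  if (diff(rng) == 0) return(NULL) # undefined for constant input
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(values, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  W <- cumsum(p); S <- cumsum(p * mids)
  csq <- function(i, j) { # (sum p mu)^2 / sum p over bins (i, j]
    w <- W[j] - if (i > 0) W[i] else 0
    s <- S[j] - if (i > 0) S[i] else 0
    ifelse(w > 0, s^2 / w, 0)
  }
  k <- n_classes - 1
  finish <- function(tbins) {
    mu_T <- S[n_bins]
    b <- c(0, tbins, n_bins)
    between <- sum(vapply(seq_len(length(b) - 1),
                          function(i) csq(b[i], b[i + 1]), 0)) - mu_T^2
    total <- sum(p * mids^2) - mu_T^2
    structure(br[tbins + 1], eta = if (total > 0) between / total else 1)
  }
  # the objective plateaus across empty histogram gaps; take the middle of
  # the tied maximizers (the conventional gap-centered threshold)
  tie_tol <- function(x) max(x) * (1 - 1e-12)
  if (k == 1) {
    obj <- vapply(seq_len(n_bins - 1), function(t) csq(0, t) + csq(t, n_bins), 0)
    ties <- which(obj >= tie_tol(obj))
    return(finish(ties[ceiling(length(ties) / 2)]))
  }
  if (k == 2) {
    best <- -Inf; tied <- list()
    for (t1 in seq_len(n_bins - 2)) {
      v1 <- csq(0, t1)
      t2s <- (t1 + 1):(n_bins - 1)
      obj <- v1 + vapply(t2s, function(t2) csq(t1, t2) + csq(t2, n_bins), 0)
      m <- which(obj >= tie_tol(c(best, obj)))
      if (length(m) > 0) {
        if (max(obj) > best * (1 + 1e-12)) { best <- max(obj); tied <- list() }
        for (mm in m) tied[[length(tied) + 1]] <- c(t1, t2s[mm])
      }
    }
    return(finish(tied[[ceiling(length(tied) / 2)]]))
  }
  # higher class counts: exhaustive search on a reduced histogram
  nb <- min(n_bins, 64)
  if (nb != n_bins) return(otsu_thresholds(values, n_classes, nb))
  combs <- utils::combn(nb - 1, k)
  obj <- apply(combs, 2, function(ts) {
    b <- c(0, ts, nb)
    sum(vapply(seq_len(length(b) - 1), function(i) csq(b[i], b[i + 1]), 0))
  })
  finish(combs[, which.max(obj)])
}

#' Per-slice multilevel Otsu surface segmentation
#'
#' Applies multilevel Otsu thresholding to each z-slice of a volume;
#' voxels in the top intensity class are foreground. Slices where the
#' threshold is undefined or unreliable — constant slices, and slices
#' whose best split has a separability (between-class over total
#' variance) below `min_separability`, as happens when a slice contains
#' only background noise — inherit the nearest resolved slice's
#' thresholds; this is recorded in the provenance attribute.
#'
#' @param vol An [image_volume()].
#' @param n_classes Number of Otsu classes (>= 2, default 3).
#' @param min_separability Minimum Otsu effectiveness (eta) for a slice's
#'   own threshold to be trusted; unimodal noise cannot exceed about
#'   0.64, well-separated foreground/background approaches 1.
#' @return A binary [image_volume()] (0/1 intensities) with a
#'   `provenance` attribute: a data frame of per-slice thresholds, the
#'   separability `eta`, and an `inherited` flag.
#' @export
segment_surface <- function(vol, n_classes = 3, min_separability = 0.75) {
  stopifnot(inherits(vol, "image_volume"))
  if (n_classes < 2) stop("n_classes must be >= 2")
  d <- dim(vol$data)
  thr <- vector("list", d[3])
  eta <- rep(NA_real_, d[3])
  for (z in seq_len(d[3])) {
    tz <- otsu_thresholds(as.numeric(vol$data[, , z]), n_classes)
    if (!is.null(tz)) {
      eta[z] <- attr(tz, "eta")
      if (eta[z] < min_separability) tz <- NULL
    }
    thr[z] <- list(tz)
  }
  undefined <- vapply(thr, is.null, TRUE)
  if (all(undefined)) stop("all slices are constant; threshold undefined")
  resolved <- which(!undefined)
  inherited <- undefined
  for (z in which(undefined)) {
    nearest <- resolved[which.min(abs(resolved - z))]
    thr[[z]] <- thr[[nearest]]
  }
  bin <- array(0L, dim = d)
  for (z in seq_len(d[3])) {
    top <- thr[[z]][n_classes - 1]
    bin[, , z] <- as.integer(vol$data[, , z] >= top)
  }
  out <- image_volume(bin, spacing_um = vol$spacing_um, bit_depth = 16)
  prov <- data.frame(slice = seq_len(d[3]),
                     top_threshold = vapply(thr, function(t) t[n_classes - 1], 0),
                     eta = eta,
                     inherited = inherited)
  attr(out, "provenance") <- prov
  out
}

#' Triangular surface mesh
#'
#' Vertices in micrometers, 1-based triangular faces with outward-oriented
#' normals (positive enclosed volume).
#'
#' @param vertices n x 3 numeric matrix (x, y, z in um).
#' @param faces m x 3 integer matrix of vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0 && (max(faces) > nrow(vertices) || min(faces) < 1))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, area %.4g um^2, volume %.4g um^3%s\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x), mesh_volume(x),
              if (mesh_is_watertight(x)) ", watertight" else ""))
  invisible(x)
}

#' Mesh surface area, enclosed volume, watertightness
#'
#' `mesh_area` sums triangle areas; `mesh_volume` applies the divergence
#' theorem (valid for watertight, outward-oriented meshes);
#' `mesh_is_watertight` checks that every edge is shared by exactly two
#' faces.
#'
#' @param mesh A [surface_mesh()].
#' @return Area in um^2, volume in um^3, or a logical.
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' @rdname mesh_area
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  v1 <- V[F[, 1], , drop = FALSE]
  v2 <- V[F[, 2], , drop = FALSE]
  v3 <- V[F[, 3], , drop = FALSE]
  det <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
         v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
         v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  sum(det) / 6
}

mesh_edge_counts <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' @rdname mesh_area
#' @export
mesh_is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  all(mesh_edge_counts(mesh) == 2)
}

# marching-tetrahedra mesh from a binary array; a light 3x3x3 box
# smoothing before iso-extraction at 0.5 gives sub-voxel interpolation so
# areas of smooth shapes are accurate to a few percent
mesh_from_binary <- function(arr, spacing_um, smooth = TRUE, pad = 2) {
  d <- dim(arr)
  pd <- d + 2 * pad
  padded <- array(0, dim = pd)
  padded[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(arr)
  if (smooth) {
    sm <- cpp_boxmean3d(padded, pd[1], pd[2], pd[3])
    # objects thinner than the kernel would vanish below the iso level
    if (max(sm) > 0.5) padded <- sm
  }
  m <- cpp_marching_tetrahedra(padded, pd[1], pd[2], pd[3], 0.5)
  V <- m$vertices
  if (nrow(V) == 0) stop("empty foreground: no surface to extract")
  # grid index -> physical um (voxel centers at (i - 0.5) * spacing)
  for (k in 1:3) V[, k] <- (V[, k] - pad + 0.5) * spacing_um[k]
  mesh <- surface_mesh(V, m$faces)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Extract a surface mesh from a binary volume
#'
#' Isosurface extraction (marching tetrahedra at level 0.5, after a light
#' box smoothing of the binary indicator for sub-voxel accuracy) from the
#' foreground of a segmented volume. The volume is zero-padded first, so
#' closed foregrounds give watertight meshes with outward normals; vertex
#' coordinates are in micrometers.
#'
#' @param binary A binary [image_volume()] (e.g. from [segment_surface()])
#'   or a logical/0-1 array plus `spacing_um`.
#' @param spacing_um Spacing when `binary` is a bare array.
#' @param smooth Apply the pre-smoothing (default TRUE).
#' @return A [surface_mesh()].
#' @export
extract_surface <- function(binary, spacing_um = NULL, smooth = TRUE) {
  if (inherits(binary, "image_volume")) {
    arr <- binary$data > 0
    spacing_um <- binary$spacing_um
  } else {
    arr <- binary > 0
    if (is.null(spacing_um)) stop("spacing_um required for bare arrays")
    if (length(spacing_um) == 1) spacing_um <- rep(spacing_um, 3)
  }
  if (!any(arr)) stop("empty foreground: nothing to extract")
  mesh_from_binary(arr, spacing_um, smooth = smooth)
}

#' Fill small holes in a surface mesh
#'
#' Finds boundary loops (edges referenced by exactly one face) and
#' triangulates loops with at most `max_hole_edges` edges by fan filling,
#' oriented consistently with the surrounding surface. Larger holes are
#' reported and left untouched.
#'
#' @param mesh A [surface_mesh()].
#' @param max_hole_edges Largest loop (edge count) that will be filled.
#' @return The repaired [surface_mesh()] with a `hole_report` attribute:
#'   a list with `filled` and `skipped` loop sizes.
#' @export
fill_holes <- function(mesh, max_hole_edges = 100) {
  F <- mesh$faces
  de <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)]) # directed edges
  key <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  cnt <- table(key)
  bnd <- de[cnt[key] == 1, , drop = FALSE]
  report <- list(filled = integer(0), skipped = integer(0))
  if (nrow(bnd) == 0) {
    attr(mesh, "hole_report") <- report
    return(mesh)
  }
  nxt <- split(bnd[, 2], bnd[, 1]) # walk along boundary direction
  used <- rep(FALSE, nrow(bnd))
  starts <- bnd[, 1]
  newF <- list()
  for (i in seq_len(nrow(bnd))) {
    if (used[i]) next
    loop <- c(bnd[i, 1], bnd[i, 2])
    used[i] <- TRUE
    repeat {
      cur <- loop[length(loop)]
      cand <- nxt[[as.character(cur)]]
      cand <- cand[!cand %in% loop[-1]]
      if (length(cand) == 0) break
      nx <- cand[1]
      j <- which(bnd[, 1] == cur & bnd[, 2] == nx & !used)
      if (length(j) == 0) break
      used[j[1]] <- TRUE
      if (nx == loop[1]) break
      loop <- c(loop, nx)
    }
    m <- length(loop)
    if (m < 3) next
    if (m > max_hole_edges) {
      report$skipped <- c(report$skipped, m)
      next
    }
    report$filled <- c(report$filled, m)
    # fan fill, reversing the boundary direction for consistent orientation
    for (k in 2:(m - 1)) {
      newF[[length(newF) + 1]] <- c(loop[1], loop[k + 1], loop[k])
    }
  }
  if (length(newF) > 0)
    mesh$faces <- rbind(mesh$faces, do.call(rbind, newF))
  attr(mesh, "hole_report") <- report
  mesh
}

#' Slice a watertight mesh into printer mask images
#'
#' Intersects the mesh with z-planes at one plane per layer (layer count =
#' ceiling(z-extent / layer thickness)) and rasterizes the interior of
#' each cross-section by even-odd filling at the given pixel pitch.
#'
#' @param mesh A watertight [surface_mesh()] (run [fill_holes()] first if
#'   needed).
#' @param layer_um Layer thickness, um (> 0).
#' @param pixel_um Raster pixel pitch, um (default `layer_um`).
#' @return An object of class `mask_stack`: list with `masks` (list of
#'   logical matrices, x by y), `layer_um`, `pixel_um`, `origin_um`, `z_um`.
#' @export
slice_masks <- function(mesh, layer_um, pixel_um = layer_um) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (layer_um <= 0) stop("layer_um must be > 0")
  if (!mesh_is_watertight(mesh))
    stop("mesh has boundary edges; fill holes first (see fill_holes())")
  V <- mesh$vertices; F <- mesh$faces
  zr <- range(V[, 3])
  n_layers <- ceiling((zr[2] - zr[1]) / layer_um)
  zs <- zr[1] + (seq_len(n_layers) - 0.5) * layer_um
  xr <- range(V[, 1]); yr <- range(V[, 2])
  nxp <- max(1, ceiling((xr[2] - xr[1]) / pixel_um))
  nyp <- max(1, ceiling((yr[2] - yr[1]) / pixel_um))
  xc <- xr[1] + (seq_len(nxp) - 0.5) * pixel_um
  yc <- yr[1] + (seq_len(nyp) - 0.5) * pixel_um
  # offset planes and scanlines off the voxel lattice: isosurface vertices
  # lie exactly on grid lines, which would defeat strict crossing tests
  eps <- 1e-4 * layer_um
  epsy <- 1e-4 * pixel_um

  tz <- matrix(V[t(F), 3], ncol = 3, byrow = TRUE)
  masks <- vector("list", n_layers)
  for (li in seq_len(n_layers)) {
    zp <- zs[li] + eps
    # half-open classification (z <= plane counts as "below") makes every
    # mixed triangle yield exactly one segment and every closed contour an
    # even crossing count, robust to vertices lying exactly on the plane
    below <- tz <= zp
    nb <- rowSums(below)
    cross <- which(nb == 1 | nb == 2)
    mask <- matrix(FALSE, nxp, nyp)
    if (length(cross) > 0) {
      seg <- matrix(NA_real_, length(cross), 4)
      for (si in seq_along(cross)) {
        f <- F[cross[si], ]
        pts <- matrix(NA_real_, 2, 2)
        m <- 0
        for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
          za <- V[f[e[1]], 3]; zb <- V[f[e[2]], 3]
          if ((za <= zp) != (zb <= zp)) {
            t <- (zp - za) / (zb - za)
            m <- m + 1
            pts[m, ] <- V[f[e[1]], 1:2] + t * (V[f[e[2]], 1:2] - V[f[e[1]], 1:2])
          }
        }
        if (m == 2) seg[si, ] <- c(pts[1, ], pts[2, ])
      }
      seg <- seg[stats::complete.cases(seg), , drop = FALSE]
      if (nrow(seg) > 0) {
        for (ri in seq_len(nyp)) {
          yv <- yc[ri] + epsy
          hit <- (seg[, 2] <= yv) != (seg[, 4] <= yv)
          if (!any(hit)) next
          s <- seg[hit, , drop = FALSE]
          tt <- (yv - s[, 2]) / (s[, 4] - s[, 2])
          xs <- sort(s[, 1] + tt * (s[, 3] - s[, 1]))
          if (length(xs) %% 2 == 1) xs <- xs[-length(xs)] # degenerate guard
          if (length(xs) >= 2) {
            for (k in seq(1, length(xs), by = 2)) {
              mask[xc > xs[k] & xc < xs[k + 1], ri] <- TRUE
            }
          }
        }
      }
    }
    masks[[li]] <- mask
  }
  structure(list(masks = masks, layer_um = layer_um, pixel_um = pixel_um,
                 origin_um = c(xr[1], yr[1]), z_um = zs),
            class = "mask_stack")
}

#' Total material volume of a mask stack
#'
#' @param stack A `mask_stack` from [slice_masks()].
#' @return Volume in um^3 (pixel area x layer thickness x filled pixels).
#' @export
mask_stack_volume <- function(stack) {
  stopifnot(inherits(stack, "mask_stack"))
  sum(vapply(stack$masks, sum, 0)) * stack$pixel_um^2 * stack$layer_um
}

#' Write a surface mesh as binary STL
#'
#' Coordinates are written in micrometers (STL itself is unitless).
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(F))) {
    v1 <- V[F[i, 1], ]; v2 <- V[F[i, 2], ]; v3 <- V[F[i, 3], ]
    nrm <- c((v2[2] - v1[2]) * (v3[3] - v1[3]) - (v2[3] - v1[3]) * (v3[2] - v1[2]),
             (v2[3] - v1[3]) * (v3[1] - v1[1]) - (v2[1] - v1[1]) * (v3[3] - v1[3]),
             (v2[1] - v1[1]) * (v3[2] - v1[2]) - (v2[2] - v1[2]) * (v3[1] - v1[1]))
    nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
    writeBin(as.numeric(c(nrm, v1, v2, v3)), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}
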