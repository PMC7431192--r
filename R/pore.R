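# HOLE-style pore profiling: per plane along the membrane normal, find the
# largest sphere that fits in the lumen without intersecting any heavy atom's
# van der Waals sphere; then assign pore-lining residues by tangency and
# reduce to per-residue minimum radii.

#' Default van der Waals radius set (HOLE "simple" radii)
#'
#' C 1.85, N 1.75, O 1.65, S 2.00, P 2.10 A. Hydrogens are excluded from
#' profiling altogether. Unknown elements fall back to 2.00 A.
#'
#' @return named numeric vector, element -> radius (A).
#' @export
default_vdw_set <- function() {
  c(C = 1.85, N = 1.75, O = 1.65, S = 2.00, P = 2.10)
}

.vdw_of <- function(elesy, vdw_set) {
  r <- vdw_set[toupper(elesy)]
  r[is.na(r)] <- 2.00
  unname(r)
}

# clearance f(p) = min_i (|p - x_i| - r_i); the profiler maximizes this in
# each plane. `xyz`/`rad` are the heavy atoms near the plane.
.clearance <- function(p, xyz, rad) {
  min(sqrt((xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 +
           (xyz[, 3] - p[3])^2) - rad)
}

# maximize clearance within the plane spanned by (e1, e2) through p0:
# multi-start Nelder-Mead followed by a shrinking pattern-search polish
.plane_max <- function(p0, e1, e2, xyz, rad, starts) {
  obj <- function(uv) -.clearance(p0 + uv[1] * e1 + uv[2] * e2, xyz, rad)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    o <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 400))
    if (is.null(best) || o$value < best$value) best <- o
  }
  uv <- best$par; val <- -best$value
  step <- 0.08
  while (step > 0.004) {
    moved <- FALSE
    for (d in list(c(step, 0), c(-step, 0), c(0, step), c(0, -step))) {
      cand <- uv + d
      v <- -obj(cand)
      if (v > val + 1e-9) { uv <- cand; val <- v; moved <- TRUE }
    }
    if (!moved) step <- step / 2
  }
  list(center = p0 + uv[1] * e1 + uv[2] * e2, radius = val, uv = uv)
}

#' HOLE-style pore radius profile
#'
#' Marches plane by plane along `axis` from `start`, maximizing the clearance
#' `f(p) = min_i (|p - x_i| - r_vdw,i)` over in-plane points `p` with a
#' deterministic multi-start local search seeded from the previous plane's
#' center plus a ring of 8 offsets. Marching stops in each direction when the
#' radius exceeds `bulk_cutoff` or the planes leave the atom z-range.
#' Hydrogens and HETATM records are ignored.
#'
#' @param model StructureModel.
#' @param axis pore axis (unit 3-vector); default the annotated membrane
#'   normal, or +z.
#' @param start in-lumen starting point; default the heavy-atom centroid.
#' @param step plane spacing (A), default 0.25.
#' @param seed integer; retained for optional stochastic restarts
#'   (`n_random` > 0).
#' @param bulk_cutoff radius (A) at which the march has reached bulk solvent.
#' @param vdw_set element -> radius map, default [default_vdw_set()].
#' @param n_random extra random in-plane starts per plane (default 0; the
#'   deterministic ring is usually sufficient).
#' @return object of class `PoreProfile`: `samples` (data.frame `z`, `cx`,
#'   `cy`, `cz`, `radius`, z strictly increasing), `step`, `axis`, `origin`,
#'   `seed`.
#' @export
pore_profile <- function(model, axis = NULL, start = NULL, step = 0.25,
                         seed = 1L, bulk_cutoff = 10, vdw_set = default_vdw_set(),
                         n_random = 0L) {
  a <- model$atoms
  sel <- !a$het & toupper(a$elesy) != "H"
  if (!any(sel)) stop("no heavy protein atoms")
  xyz <- atom_coords(model, sel)
  rad <- .vdw_of(a$elesy[sel], vdw_set)
  if (is.null(axis)) {
    axis <- if (!is.null(model$annotations)) model$annotations$membrane_normal
            else c(0, 0, 1)
  }
  axis <- axis / sqrt(sum(axis^2))
  if (is.null(start)) start <- colMeans(xyz)
  start <- unname(start)
  if (.clearance(start, xyz, rad) < 0)
    stop("start point lies inside an atom; supply a point in the lumen")
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  zatom <- as.numeric(xyz %*% axis)
  z0 <- sum(start * axis)
  zr <- range(zatom)
  ring <- cbind(c(0, 1, 0.7071, 0, -0.7071, -1, -0.7071, 0, 0.7071),
                c(0, 0, 0.7071, 1, 0.7071, 0, -0.7071, -1, -0.7071))
  extra <- if (n_random > 0)
    .with_seed(seed, matrix(runif(2 * n_random, -2, 2), ncol = 2)) else NULL
  march <- function(dir) {
    out <- list(); prev_uv <- c(0, 0); k <- 1L
    repeat {
      z <- z0 + dir * step * (k - 1L)
      if (z < zr[1] - step || z > zr[2] + step) break
      p0 <- start + (z - z0) * axis
      near <- abs(zatom - z) < bulk_cutoff + max(rad) + 1
      if (!any(near)) break
      starts <- rbind(sweep(ring, 2, -prev_uv), extra)
      res <- .plane_max(p0, e1, e2, xyz[near, , drop = FALSE], rad[near], starts)
      if (res$radius < 0) { k <- k + 1L; next }  # plane blocked: skip
      out[[k]] <- c(z = z, cx = res$center[1], cy = res$center[2],
                    cz = res$center[3], radius = res$radius)
      prev_uv <- res$uv
      if (res$radius > bulk_cutoff) break
      k <- k + 1L
    }
    do.call(rbind, out)
  }
  samples <- as.data.frame(rbind(march(-1), march(+1)))
  if (!nrow(samples)) stop("profiling produced no planes")
  samples <- samples[order(samples$z), , drop = FALSE]
  samples <- samples[!duplicated(samples$z), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(samples = samples, step = step, axis = axis,
                 origin = start, seed = seed),
            class = "PoreProfile")
}

#' @export
print.PoreProfile <- function(x, ...) {
  cat(sprintf("PoreProfile: %d planes, z %.1f..%.1f A, min radius %.2f A\n",
              nrow(x$samples), min(x$samples$z), max(x$samples$z),
              min(x$samples$radius)), sep = "")
  invisible(x)
}

#' Pore-lining residue assignment by sphere tangency
#'
#' Atom `i` lines the pore at plane `k` when its distance to the profile
#' center equals the atom's van der Waals radius plus the local pore radius,
#' within `tol`. A residue's minimum pore radius is the smallest profile
#' radius among the planes any of its atoms touches. Residues with no
#' tangency are omitted.
#'
#' @param model StructureModel.
#' @param profile PoreProfile.
#' @param tol tangency tolerance (A), default 0.1.
#' @param vdw_set element radii, default [default_vdw_set()].
#' @return object of class `LiningAssignment`: `min_radius` (named vector,
#'   residue key -> A) and `touches` (list, residue key -> sample indices).
#' @export
lining_residues <- function(model, profile, tol = 0.1,
                            vdw_set = default_vdw_set()) {
  a <- model$atoms
  sel <- !a$het & toupper(a$elesy) != "H"
  xyz <- atom_coords(model, sel)
  rad <- .vdw_of(a$elesy[sel], vdw_set)
  keys <- residue_key(a$chain[sel], a$resno[sel], a$insert[sel])
  s <- profile$samples
  cen <- as.matrix(s[, c("cx", "cy", "cz")])
  touches <- list(); minrad <- c()
  for (k in seq_len(nrow(s))) {
    d <- sqrt((xyz[, 1] - cen[k, 1])^2 + (xyz[, 2] - cen[k, 2])^2 +
              (xyz[, 3] - cen[k, 3])^2)
    tang <- abs(d - (rad + s$radius[k])) <= tol
    for (key in unique(keys[tang])) {
      touches[[key]] <- c(touches[[key]], k)
      minrad[key] <- min(minrad[key], s$radius[k], na.rm = TRUE)
    }
  }
  structure(list(min_radius = minrad, touches = touches),
            class = "LiningAssignment")
}

#' Minimum pore radius over a window
#'
#' For a `PoreProfile`, the window is a z range; for a `LiningAssignment`,
#' a residue-number range (taken over all chains).
#'
#' @param x PoreProfile or LiningAssignment.
#' @param window length-2 numeric: `c(zmin, zmax)` for a profile,
#'   `c(resno_min, resno_max)` for a lining assignment. `NULL` = whole range.
#' @return minimum radius (A); `NA` if the window is empty.
#' @export
window_min_radius <- function(x, window = NULL) {
  if (inherits(x, "PoreProfile")) {
    s <- x$samples
    if (!is.null(window)) s <- s[s$z >= window[1] & s$z <= window[2], ]
    if (!nrow(s)) return(NA_real_)
    return(min(s$radius))
  }
  if (inherits(x, "LiningAssignment")) {
    mr <- x$min_radius
    if (!is.null(window)) {
      resno <- as.integer(sub("^[^:]*:(-?[0-9]+):.*$", "\\1", names(mr)))
      mr <- mr[resno >= window[1] & resno <= window[2]]
    }
    if (!length(mr)) return(NA_real_)
    return(min(mr))
  }
  stop("x must be a PoreProfile or LiningAssignment")
}

#' Classify a constriction radius against hydrated/dehydrated ion sizes
#'
#' Thresholds: below 1.0 A not even dehydrated cations pass
#' (`sub-dehydrated`); 1.0-3.3 A only dehydrated ions (`dehydrated-only`);
#' 3.3-4.1 A admits hydrated Na+ (`hydrated-Na`); at or above 4.1 A admits
#' hydrated Ca2+ (`hydrated-Ca`). Lower bounds inclusive.
#'
#' @param radius numeric vector of radii (A).
#' @param thresholds named vector `c(dehydrated = 1.0, na_hydrated = 3.3,
#'   ca_hydrated = 4.1)`.
#' @return character vector of labels.
#' @export
classify_conduction <- function(radius,
                                thresholds = c(dehydrated = 1.0,
                                               na_hydrated = 3.3,
                                               ca_hydrated = 4.1)) {
  cut_labels <- c("sub-dehydrated", "dehydrated-only", "hydrated-Na",
                  "hydrated-Ca")
  idx <- findInterval(radius, thresholds) + 1L
  cut_labels[idx]
}

#' Write a pore profile as CSV
#' @param profile PoreProfile.
#' @param path output path.
#' @param comment optional `#` comment line.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path, comment = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(profile$samples, con, row.names = FALSE)
  invisible(path)
}
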