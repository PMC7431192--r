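# Synthetic structure generators. Every downstream stage of the pipeline is
# exercised on these fixtures: ideal helices with class-specific geometry,
# C4-symmetric four-helix pseudo-pores with analytic radius profiles, planted
# pseudo-ligands at controlled distances, and rigid+noise perturbed copies
# with known fold relationships. All generators are deterministic given seed.

# -- internal: NeRF atom placement -------------------------------------------
# place atom D given A-B-C with bond |CD|, angle B-C-D (deg), torsion A-B-C-D (deg)
.place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m2 + d2[3] * n
}

# standard backbone internal coordinates
.bb <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.8, omega = 180)

# dihedral-based CB placement (ideal tetrahedral geometry from N, CA, C)
.place_cb <- function(n, ca, c) {
  b <- ca - n; cc <- c - ca
  a <- c(b[2] * cc[3] - b[3] * cc[2],
         b[3] * cc[1] - b[1] * cc[3],
         b[1] * cc[2] - b[2] * cc[1])
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

#' Helix geometry specification
#'
#' Default per-class rise/twist follow the canonical helix parameters:
#' alpha 1.5 A and 100 deg per residue (3.6 residues/turn), 3-10 helix 2.0 A
#' and 120 deg (3 residues/turn), pi helix 1.1 A and ~87 deg
#' (4.6 residues/turn). The backbone itself is generated from the class's
#' canonical (phi, psi) dihedrals, which realize these parameters.
#'
#' @param helix_class `"alpha"`, `"three_ten"` or `"pi"`.
#' @param n_res residue count.
#' @param rise,twist override the class defaults (A/residue, deg/residue).
#' @return list of class `HelixSpec`.
#' @export
helix_spec <- function(helix_class = c("alpha", "three_ten", "pi"),
                       n_res = 20, rise = NULL, twist = NULL) {
  helix_class <- match.arg(helix_class)
  defaults <- switch(helix_class,
    alpha     = list(rise = 1.5, twist = 100,  phi = -57.8, psi = -47.0),
    three_ten = list(rise = 2.0, twist = 120,  phi = -49.0, psi = -26.0),
    pi        = list(rise = 1.1, twist = 360 / 4.6, phi = -55.0, psi = -70.0))
  structure(list(helix_class = helix_class, n_res = n_res,
                 rise = if (is.null(rise)) defaults$rise else rise,
                 twist = if (is.null(twist)) defaults$twist else twist,
                 phi = defaults$phi, psi = defaults$psi),
            class = "HelixSpec")
}

#' Build an ideal helix with full backbone
#'
#' Generates N, CA, C, O (and CB for non-Gly) atoms by sequential placement
#' with standard bond geometry and the class's canonical dihedrals, so that
#' the hydrogen-bonding pattern read by [assign_secstruct()] reproduces the
#' intended helix class.
#'
#' @param spec [helix_spec()].
#' @param sequence 1-letter amino-acid string of length `n_res`
#'   (default poly-Ala).
#' @param chain chain id.
#' @param start_resno first residue number.
#' @return StructureModel.
#' @export
make_ideal_helix <- function(spec, sequence = NULL, chain = "A",
                             start_resno = 1L) {
  n <- spec$n_res
  if (is.null(sequence)) sequence <- strsplit(paste(rep("A", n), collapse = ""), "")[[1]]
  else sequence <- strsplit(sequence, "")[[1]]
  stopifnot(length(sequence) == n)
  res3 <- suppressWarnings(bio3d::aa123(sequence))
  res3[is.na(res3)] <- "UNK"
  bb <- .bb
  # seed atoms for residue 1
  Npos <- list(); CApos <- list(); Cpos <- list(); Opos <- list()
  Npos[[1]] <- c(0, 0, 0)
  CApos[[1]] <- c(bb$n_ca, 0, 0)
  ang <- bb$ang_n_ca_c * pi / 180
  Cpos[[1]] <- CApos[[1]] + bb$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      Npos[[i]] <- .place_atom(Npos[[i - 1]], CApos[[i - 1]], Cpos[[i - 1]],
                               bb$c_n, bb$ang_ca_c_n, spec$psi)
      CApos[[i]] <- .place_atom(CApos[[i - 1]], Cpos[[i - 1]], Npos[[i]],
                                bb$n_ca, bb$ang_c_n_ca, bb$omega)
      Cpos[[i]] <- .place_atom(Cpos[[i - 1]], Npos[[i]], CApos[[i]],
                               bb$ca_c, bb$ang_n_ca_c, spec$phi)
    }
    # carbonyl O in the peptide plane: torsion N-CA-C-O = psi + 180
    Opos[[i]] <- .place_atom(Npos[[i]], CApos[[i]], Cpos[[i]],
                             bb$c_o, bb$ang_ca_c_o, spec$psi + 180)
  }
  rows <- list()
  for (i in seq_len(n)) {
    resno <- start_resno + i - 1L
    at <- rbind(N = Npos[[i]], CA = CApos[[i]], C = Cpos[[i]], O = Opos[[i]])
    if (sequence[i] != "G")
      at <- rbind(at, CB = .place_cb(Npos[[i]], CApos[[i]], Cpos[[i]]))
    rows[[i]] <- data.frame(chain = chain, resno = resno, insert = "",
                            resname = res3[i], elety = rownames(at),
                            elesy = substr(rownames(at), 1, 1),
                            x = at[, 1], y = at[, 2], z = at[, 3],
                            het = FALSE, o = 1, stringsAsFactors = FALSE)
  }
  structure_model(do.call(rbind, rows), pdb_id = paste0("hx_", spec$helix_class))
}

#' Pore wall specification for the synthetic tetramer
#'
#' @param radial_profile data.frame with columns `z` (A) and `wall_radius`
#'   (A, distance from pore axis to wall-atom centers); linearly interpolated
#'   between knots.
#' @param symmetry rotational order (4 = tetramer).
#' @param atom_vdw van der Waals radius assigned to the wall pseudo-atoms.
#' @return list of class `PoreSpec`.
#' @export
pore_spec <- function(radial_profile, symmetry = 4L, atom_vdw = 1.85) {
  stopifnot(all(c("z", "wall_radius") %in% names(radial_profile)),
            all(radial_profile$wall_radius > atom_vdw))
  radial_profile <- radial_profile[order(radial_profile$z), , drop = FALSE]
  structure(list(radial_profile = radial_profile, symmetry = as.integer(symmetry),
                 atom_vdw = atom_vdw), class = "PoreSpec")
}

#' Build a C\eqn{_n}-symmetric pseudo-atom pore wall
#'
#' Places carbon pseudo-atoms on rings of radius `wall_radius(z)` every
#' `dz` along z, with in-ring arc spacing ~`arc` A, split into `symmetry`
#' chains by angular sector (one residue per ring per chain). The analytic
#' pore radius at a ring plane is `wall_radius(z) - atom_vdw`. The analytic
#' profile is attached as attribute `ground_truth`.
#'
#' @param spec [pore_spec()].
#' @param dz ring spacing (A), default 0.25.
#' @param arc target in-ring atom spacing (A), default 0.6.
#' @return StructureModel with exact C\eqn{_n} symmetry.
#' @export
make_tetramer_pore <- function(spec, dz = 0.25, arc = 0.6) {
  prof <- spec$radial_profile
  zs <- seq(min(prof$z), max(prof$z), by = dz)
  wall <- stats::approx(prof$z, prof$wall_radius, xout = zs)$y
  nsym <- spec$symmetry
  chains <- LETTERS[seq_len(nsym)]
  rows <- vector("list", length(zs))
  for (k in seq_along(zs)) {
    w <- wall[k]
    # per-sector atom count so that full-ring spacing is <= arc; exact C_n
    per <- max(4L, ceiling((2 * pi * w / nsym) / arc))
    th0 <- (seq_len(per) - 1) * (2 * pi / nsym) / per
    sector <- lapply(seq_len(nsym), function(s) {
      th <- th0 + (s - 1) * 2 * pi / nsym
      data.frame(chain = chains[s], resno = k, insert = "", resname = "UNK",
                 elety = sprintf("C%02d", seq_len(per)), elesy = "C",
                 x = w * cos(th), y = w * sin(th), z = zs[k],
                 het = FALSE, o = 1, stringsAsFactors = FALSE)
    })
    rows[[k]] <- do.call(rbind, sector)
  }
  m <- structure_model(do.call(rbind, rows), pdb_id = "synthpore",
                       annotations = structure_annotation(
                         membrane_normal = c(0, 0, 1), extracellular_sign = 1))
  attr(m, "ground_truth") <- list(z = zs, analytic_radius = wall - spec$atom_vdw,
                                  atom_vdw = spec$atom_vdw)
  m
}

#' Plant a pseudo-ligand at a controlled side-chain distance
#'
#' Adds a one-atom HETATM group whose nearest approach to the named residue's
#' side chain equals `distance` (within 0.01 A), placed along the outward
#' direction from the model centroid through the residue's outermost
#' side-chain atom.
#'
#' @param model StructureModel.
#' @param target_residue residue key (`chain:resno:insert`).
#' @param distance target nearest-approach distance (A).
#' @param resname HETATM residue name (default `"LIG"`).
#' @return StructureModel with the ligand appended.
#' @export
plant_ligand <- function(model, target_residue, distance, resname = "LIG") {
  a <- model$atoms
  key <- residue_key(a$chain, a$resno, a$insert)
  sc <- !a$het & key == target_residue &
    !(a$elety %in% c("N", "CA", "C", "O")) & a$elesy != "H"
  if (!any(sc)) stop("residue ", target_residue, " has no side-chain atoms")
  centroid <- colMeans(atom_coords(model, !a$het))
  scx <- atom_coords(model, sc)
  d_out <- sqrt(rowSums(sweep(scx, 2, centroid)^2))
  anchor <- scx[which.max(d_out), ]
  u <- anchor - centroid; u <- u / sqrt(sum(u^2))
  pos <- anchor + distance * u
  # verify nearest approach: another side-chain atom of the residue could
  # intrude; nudge outward until the minimum distance matches
  for (it in 1:50) {
    dmin <- min(sqrt(rowSums(sweep(scx, 2, pos)^2)))
    if (abs(dmin - distance) <= 0.01) break
    pos <- pos + (distance - dmin) * u
  }
  lig <- data.frame(chain = "X", resno = 999L, insert = "", resname = resname,
                    elety = "C1", elesy = "C",
                    x = pos[1], y = pos[2], z = pos[3],
                    het = TRUE, o = 1, stringsAsFactors = FALSE)
  model$atoms <- rbind(model$atoms, lig)
  rownames(model$atoms) <- NULL
  model
}

# run expr with a private RNG stream; global .Random.seed untouched
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Rigid-transformed, noise-perturbed copy of a model
#'
#' Applies a rigid rotation+translation and then i.i.d. Gaussian coordinate
#' noise. Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param model StructureModel.
#' @param rotation 3x3 proper rotation (default random, seed-derived).
#' @param translation length-3 vector (default random in \[-20, 20\]).
#' @param noise_sd per-coordinate Gaussian sd (A).
#' @param seed integer.
#' @return perturbed StructureModel.
#' @export
perturb_copy <- function(model, rotation = NULL, translation = NULL,
                         noise_sd = 0, seed = 1L) {
  .with_seed(seed, {
    if (is.null(rotation)) rotation <- random_rotation()
    if (is.null(translation)) translation <- runif(3, -20, 20)
    out <- transform_model(model, rotation, translation)
    if (!is.null(out$annotations))  # keep the membrane frame attached
      out$annotations$membrane_normal <-
        as.numeric(rotation %*% out$annotations$membrane_normal)
    if (noise_sd > 0) {
      n <- nrow(out$atoms)
      out$atoms$x <- out$atoms$x + rnorm(n, 0, noise_sd)
      out$atoms$y <- out$atoms$y + rnorm(n, 0, noise_sd)
      out$atoms$z <- out$atoms$z + rnorm(n, 0, noise_sd)
    }
    out$pdb_id <- paste0(model$pdb_id, "_p", seed)
    out
  })
}

#' Uniform random proper rotation (uses the current RNG stream)
#' @return 3x3 rotation matrix, det +1.
#' @export
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Random compact protein-like CA fold
#'
#' Chains together ideal alpha-helical CA segments (6-18 residues) joined by
#' short random-walk linkers, confined to a sphere of radius
#' `3.0 * n_res^(1/3)` (protein-like packing density). Used as the
#' unrelated-fold baseline for alignment statistics.
#'
#' @param n_res residue count.
#' @param seed integer.
#' @param chain chain id.
#' @return CA-only StructureModel with random sequence.
#' @export
make_random_fold <- function(n_res = 150L, seed = 1L, chain = "A") {
  .with_seed(seed, {
    R <- 3.0 * n_res^(1 / 3)
    xyz <- matrix(NA_real_, n_res, 3)
    xyz[1, ] <- runif(3, -2, 2)
    i <- 1L
    # ideal alpha CA helix: radius 2.3 A, rise 1.5 A, 100 deg/res
    while (i < n_res) {
      seg <- sample(6:18, 1)
      rot <- random_rotation()
      t0 <- runif(1, 0, 2 * pi)
      local <- t(vapply(seq_len(seg), function(k) {
        th <- t0 + (k - 1) * 100 * pi / 180
        c(2.3 * cos(th), 2.3 * sin(th), (k - 1) * 1.5)
      }, numeric(3)))
      local <- local %*% t(rot)
      shift <- xyz[i, ] - local[1, ]
      take <- min(seg - 1L, n_res - i)
      cand <- sweep(local[1 + seq_len(take), , drop = FALSE], 2, -shift)
      # keep the fold compact: reflect segments leaving the sphere
      if (any(sqrt(rowSums(cand^2)) > R)) next
      xyz[i + seq_len(take), ] <- cand
      i <- i + take
      if (i < n_res) {  # 2-residue linker, random direction inward-biased
        for (l in 1:2) {
          if (i >= n_res) break
          repeat {
            d <- rnorm(3); d <- d / sqrt(sum(d^2))
            p <- xyz[i, ] + 3.8 * d
            if (sqrt(sum(p^2)) <= R) break
          }
          xyz[i + 1, ] <- p; i <- i + 1L
        }
      }
    }
    aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
    seq1 <- sample(aas, n_res, replace = TRUE)
    res3 <- bio3d::aa123(seq1)
    atoms <- data.frame(chain = chain, resno = seq_len(n_res), insert = "",
                        resname = res3, elety = "CA", elesy = "C",
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        het = FALSE, o = 1, stringsAsFactors = FALSE)
    structure_model(atoms, pdb_id = sprintf("rf%04d", seed %% 10000))
  })
}

#' Synthetic tetrameric channel with annotated domains
#'
#' Assembles a C4 tetramer from one protomer of six ideal alpha helices
#' (S1-S6 analogues) arranged around the z axis, with short loops. Residue
#' numbering and annotations (TM segments, domain bounds) are laid out so
#' that domain extraction, loop truncation and pore profiling all operate as
#' on a real channel. A seed-controlled backbone jitter distinguishes family
#' members.
#'
#' @param pdb_id label.
#' @param seed integer controlling the protomer jitter.
#' @param jitter_sd coordinate jitter sd (A) applied to the protomer before
#'   symmetrization (keeps C4 symmetry).
#' @param helix_len residues per TM helix.
#' @param ligand_state annotation label.
#' @return StructureModel (4 chains) with full annotations.
#' @export
make_synthetic_channel <- function(pdb_id = "syn1", seed = 1L, jitter_sd = 0,
                                   helix_len = 18L, ligand_state = "apo") {
  .with_seed(seed, {
    hx <- lapply(1:6, function(h) {
      m <- make_ideal_helix(helix_spec("alpha", n_res = helix_len),
                            start_resno = (h - 1L) * (helix_len + 2L) + 1L)
      m
    })
    # helix placement per protomer quadrant: S1-S4 bundle on an outer ring,
    # S5/S6 lining the central pore at ~8 A so the lumen stays open
    r_ring <- c(17, 17, 17, 17, 8.5, 8.0)
    th_deg <- c(10, 35, 60, 85, 20, 65)
    prot <- vector("list", 6)
    for (h in 1:6) {
      m <- hx[[h]]
      xyz <- atom_coords(m)
      xyz <- sweep(xyz, 2, colMeans(xyz))
      # helix axis along z, alternate up/down
      if (h %% 2 == 0) xyz[, 3] <- -xyz[, 3]
      th <- th_deg[h] * pi / 180
      xyz[, 1] <- xyz[, 1] + r_ring[h] * cos(th)
      xyz[, 2] <- xyz[, 2] + r_ring[h] * sin(th)
      m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
      prot[[h]] <- m$atoms
    }
    pa <- do.call(rbind, prot)
    if (jitter_sd > 0) {
      pa$x <- pa$x + rnorm(nrow(pa), 0, jitter_sd)
      pa$y <- pa$y + rnorm(nrow(pa), 0, jitter_sd)
      pa$z <- pa$z + rnorm(nrow(pa), 0, jitter_sd)
    }
    chains <- c("A", "B", "C", "D")
    tet <- lapply(1:4, function(s) {
      th <- (s - 1) * pi / 2
      rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                    3, 3, byrow = TRUE)
      xyz <- as.matrix(pa[, c("x", "y", "z")]) %*% t(rot)
      out <- pa
      out$chain <- chains[s]
      out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
      out
    })
    L <- helix_len; gap <- 2L
    seg <- data.frame(start = (0:5) * (L + gap) + 1L, end = (0:5) * (L + gap) + L)
    ann <- structure_annotation(
      subfamily = "synthetic", method = "model", environment = "none",
      ligand_state = ligand_state,
      membrane_normal = c(0, 0, 1), extracellular_sign = 1,
      tm_segments = seg,
      domain_bounds = list(TM = c(seg$start[1], seg$end[6]),
                           pore = c(seg$start[5], seg$end[6]),
                           S1S4 = c(seg$start[1], seg$end[4])))
    m <- structure_model(do.call(rbind, tet), pdb_id = pdb_id,
                         resolution = 3.0, annotations = ann)
    m
  })
}

#' Family of perturbed channel copies with known relationships
#'
#' @param base StructureModel.
#' @param n copies.
#' @param noise_sd coordinate noise (A).
#' @param seed integer; copy k uses `seed + k`.
#' @return named list of StructureModel.
#' @export
make_family <- function(base, n = 3L, noise_sd = 0.3, seed = 100L) {
  out <- lapply(seq_len(n), function(k) {
    m <- perturb_copy(base, noise_sd = noise_sd, seed = seed + k)
    m$pdb_id <- sprintf("%s_f%d", base$pdb_id, k)
    m
  })
  names(out) <- vapply(out, function(m) m$pdb_id, character(1))
  out
}

#' Write the ground-truth sidecar of a fixture as JSON
#' @param model fixture with a `ground_truth` attribute.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(model, path) {
  gt <- attr(model, "ground_truth")
  if (is.null(gt)) stop("model carries no ground truth")
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
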