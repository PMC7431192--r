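# Independent oracles and small fixture builders shared across the suite.
# Oracles deliberately avoid the package's computational paths: rotation
# search instead of SVD, plain-R dynamic programming, dense grid search.

# ---- rotation-search RMSD oracle (no SVD) -----------------------------------
# coarse quaternion grid, then Nelder-Mead polish on the axis-angle vector
oracle_superpose_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rot_of <- function(v) {  # axis-angle (Rodrigues)
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  rmsd_of <- function(v) {
    R <- rot_of(v)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  best <- c(0, 0, 0); bval <- rmsd_of(best)
  gs <- seq(-pi, pi, length.out = 9)
  for (a in gs) for (b in gs) for (c in gs) {
    v <- c(a, b, c)
    if (sqrt(sum(v^2)) > pi + 1e-9) next
    val <- rmsd_of(v)
    if (val < bval) { bval <- val; best <- v }
  }
  o <- stats::optim(best, rmsd_of, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 2000))
  o <- stats::optim(o$par, rmsd_of, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 2000))
  o$value
}

# ---- plain-R alignment oracle ----------------------------------------------
oracle_kabsch <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- t(sweep(P, 2, pc)) %*% sweep(Q, 2, qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = qc - as.numeric(R %*% pc))
}

oracle_tm_refine <- function(Pm, Ps, d0) {
  n <- nrow(Pm)
  apply_rt <- function(X, R, t) sweep(X %*% t(R), 2, -t)
  tmsum <- function(R, t) {
    d2 <- rowSums((apply_rt(Pm, R, t) - Ps)^2)
    sum(1 / (1 + d2 / d0^2))
  }
  best <- -1; Rb <- diag(3); tb <- c(0, 0, 0)
  lens <- c(); L <- n
  while (L >= 4) { lens <- c(lens, L); L <- L %/% 2 }
  d_cut0 <- max(4.5, d0)
  for (L in lens) {
    for (st in seq(1, n - L + 1, by = max(1, L %/% 2))) {
      k <- oracle_kabsch(Pm[st:(st + L - 1), , drop = FALSE],
                         Ps[st:(st + L - 1), , drop = FALSE])
      R <- k$R; t <- k$t
      prev <- integer(); d_cut <- d_cut0
      for (it in 1:30) {
        d2 <- rowSums((apply_rt(Pm, R, t) - Ps)^2)
        sel <- which(d2 < d_cut^2)
        if (length(sel) < 3) { d_cut <- d_cut + 0.5; next }
        s <- tmsum(R, t)
        if (s > best) { best <- s; Rb <- R; tb <- t }
        if (length(sel) == length(prev) && all(sel == prev)) break
        prev <- sel
        k <- oracle_kabsch(Pm[sel, , drop = FALSE], Ps[sel, , drop = FALSE])
        R <- k$R; t <- k$t
      }
    }
  }
  list(tm_sum = best, R = Rb, t = tb)
}

oracle_dp <- function(S, gap) {
  n <- nrow(S); m <- ncol(S)
  F <- matrix(0, n + 1, m + 1)
  P <- matrix(0L, n + 1, m + 1)
  for (i in 1:n) for (j in 1:m) {
    diag_ <- F[i, j] + S[i, j]
    up <- F[i, j + 1] - gap
    left <- F[i + 1, j] - gap
    v <- diag_; p <- 1L
    if (up > v) { v <- up; p <- 2L }
    if (left > v) { v <- left; p <- 3L }
    F[i + 1, j + 1] <- v; P[i + 1, j + 1] <- p
  }
  bi <- n + 1; bj <- m + 1; bv <- F[n + 1, m + 1]
  for (j in 1:(m + 1)) if (F[n + 1, j] > bv) { bv <- F[n + 1, j]; bi <- n + 1; bj <- j }
  for (i in 1:(n + 1)) if (F[i, m + 1] > bv) { bv <- F[i, m + 1]; bi <- i; bj <- m + 1 }
  mi <- integer(); mj <- integer()
  i <- bi; j <- bj
  while (i > 1 && j > 1) {
    p <- P[i, j]
    if (p == 1L) { mi <- c(i - 1, mi); mj <- c(j - 1, mj); i <- i - 1; j <- j - 1 }
    else if (p == 2L) i <- i - 1
    else j <- j - 1
  }
  cbind(mi, mj)
}

# exhaustive-seed alignment oracle: every gapless fragment pair (length F,
# stride 1) seeds an iterated superpose/score/DP loop; the best final
# stationary-normalized TM wins
oracle_fragment_align <- function(xm, xs, F = 4, gap = 0.6, max_iter = 20) {
  n <- nrow(xm); m <- nrow(xs)
  d0 <- channelstruct::tm_d0(m)
  apply_rt <- function(X, R, t) sweep(X %*% t(R), 2, -t)
  best <- list(tm = -1)
  for (i in 1:(n - F + 1)) for (j in 1:(m - F + 1)) {
    k <- oracle_kabsch(xm[i:(i + F - 1), , drop = FALSE],
                       xs[j:(j + F - 1), , drop = FALSE])
    R <- k$R; t <- k$t
    # stage-1 round mirrors the seeding contract
    map <- NULL
    for (it in 1:max_iter) {
      Xt <- apply_rt(xm, R, t)
      d2 <- pmax(outer(rowSums(Xt^2), rowSums(xs^2), "+") - 2 * Xt %*% t(xs), 0)
      S <- 1 / (1 + d2 / d0^2)
      nmap <- oracle_dp(S, gap)
      if (nrow(nmap) < 3) { map <- NULL; break }
      same <- !is.null(map) && nrow(map) == nrow(nmap) && all(map == nmap)
      map <- nmap
      ref <- oracle_tm_refine(xm[map[, 1], , drop = FALSE],
                              xs[map[, 2], , drop = FALSE], d0)
      R <- ref$R; t <- ref$t
      if (same) break
    }
    if (is.null(map)) next
    ref <- oracle_tm_refine(xm[map[, 1], , drop = FALSE],
                            xs[map[, 2], , drop = FALSE], d0)
    tm <- ref$tm_sum / m
    if (tm > best$tm) best <- list(tm = tm, mapping = map)
  }
  best
}

# ---- dense-grid pore oracle -------------------------------------------------
# clearance maximum in the plane z = z0 by exhaustive 2-D grid search
oracle_plane_radius <- function(model, z0, half_width = 2.5, spacing = 0.02,
                                vdw = 1.85) {
  a <- model$atoms
  sel <- !a$het
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  near <- abs(xyz[, 3] - z0) < 12
  xyz <- xyz[near, , drop = FALSE]
  g <- seq(-half_width, half_width, by = spacing)
  best <- -Inf
  for (gx in g) {
    d2 <- (xyz[, 1] - gx)^2 + outer(xyz[, 2], g, "-")^2 + (xyz[, 3] - z0)^2
    f <- apply(sqrt(d2), 2, min) - vdw
    if (max(f) > best) best <- max(f)
  }
  best
}

# ---- Kabsch-Sander energy straight from the formula -------------------------
oracle_ks_energy <- function(Npos, Hpos, Cpos, Opos) {
  r <- function(u, v) sqrt(sum((u - v)^2))
  0.084 * 332 * (1 / r(Opos, Npos) + 1 / r(Cpos, Hpos) -
                 1 / r(Opos, Hpos) - 1 / r(Cpos, Npos))
}

# ---- fixture builders -------------------------------------------------------
# single-chain CA model from a coordinate matrix
ca_model <- function(xyz, id = "toy", resname = "ALA", chain = "A") {
  n <- nrow(xyz)
  structure_model(data.frame(chain = chain, resno = seq_len(n), insert = "",
                             resname = resname, elety = "CA", elesy = "C",
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                             het = FALSE, o = 1, stringsAsFactors = FALSE),
                  pdb_id = id)
}

# CA-only model with TM-segment annotations and a loop of chosen length
loop_model <- function(loop_len, seg_len = 20) {
  n <- seg_len * 2 + loop_len
  xyz <- cbind(seq_len(n) * 1.2, 0, 0)
  m <- ca_model(xyz, id = "loopy")
  m$annotations <- structure_annotation(
    tm_segments = data.frame(start = c(1, seg_len + loop_len + 1),
                             end = c(seg_len, n)),
    domain_bounds = list(TM = c(1, n), pore = c(1, n), S1S4 = c(1, seg_len)))
  m
}

# hand-built StructuralMSA for motif unit tests
tiny_msa <- function(rows, reference_id = rownames(rows)[1]) {
  ncol_ <- ncol(rows)
  cols <- residue_key("A", seq_len(ncol_))
  prov <- matrix(NA_character_, nrow(rows), ncol_,
                 dimnames = list(rownames(rows), cols))
  for (i in seq_len(nrow(rows)))
    prov[i, rows[i, ] != "-"] <- cols[rows[i, ] != "-"]
  colnames(rows) <- cols
  structure(list(reference_id = reference_id, columns = cols,
                 rows = rows, provenance = prov), class = "StructuralMSA")
}
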