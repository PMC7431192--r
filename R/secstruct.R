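# DSSP-style secondary-structure assignment restricted to the helix ladder
# (H = alpha, G = 3-10, I = pi, T = turn), which is what transmembrane-helix
# surveys need. Hydrogen-bond detection uses the Kabsch-Sander electrostatic
# model with amide H reconstructed from the preceding peptide geometry.

#' DSSP-style secondary-structure assignment
#'
#' Hydrogen bonds are scored with the Kabsch-Sander energy
#' `E = 0.084 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) * 332` kcal/mol between
#' each donor N-H and acceptor C=O, with a bond called at `E < -0.5`. The
#' amide H is reconstructed 1.0 A from N opposite the preceding residue's
#' C=O. An n-turn at residue `i` is a bond from donor `i+n` to acceptor `i`
#' (n = 3, 4, 5); two consecutive n-turns start a helix of the corresponding
#' class, with ladder precedence H > G > I. Residues in a turn but no helix
#' are `T`; all else `-`. Chain breaks (CA-CA > 4.5 A) are treated as
#' termini. Strand and bend codes are not assigned.
#'
#' @param model StructureModel with backbone N, CA, C, O atoms.
#' @return object of class `SecStructAssignment`: `codes` (named character
#'   vector, residue key -> code in `H G I T -`) and `hbonds` (data.frame
#'   `donor`, `acceptor` residue keys and `energy` kcal/mol for all bonds
#'   with `E < -0.5`).
#' @export
assign_secstruct <- function(model) {
  rt <- residue_table(model)
  n <- nrow(rt)
  get_bb <- function(elety) {
    a <- model$atoms
    sel <- !a$het & a$elety == elety
    key <- residue_key(a$chain[sel], a$resno[sel], a$insert[sel])
    m <- matrix(NA_real_, n, 3)
    idx <- match(rt$key, key)
    hit <- !is.na(idx)
    m[hit, ] <- as.matrix(a[sel, c("x", "y", "z")])[idx[hit], , drop = FALSE]
    m
  }
  N <- get_bb("N"); CA <- get_bb("CA"); C <- get_bb("C"); O <- get_bb("O")
  # chain breaks: different chain or CA-CA > 4.5 A
  brk <- rep(FALSE, n)  # brk[i]: break between i-1 and i
  if (n > 1) {
    d <- sqrt(rowSums((CA[-1, , drop = FALSE] - CA[-n, , drop = FALSE])^2))
    brk[-1] <- rt$chain[-1] != rt$chain[-n] | is.na(d) | d > 4.5
  }
  # amide H from preceding residue's C=O; none at segment starts
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (i == 1 || brk[i]) next
    u <- C[i - 1, ] - O[i - 1, ]
    nu <- sqrt(sum(u^2))
    if (!is.finite(nu) || nu == 0) next
    H[i, ] <- N[i, ] + u / nu
  }
  # Kabsch-Sander energies for all donor/acceptor pairs |i-j| >= 2
  q <- 0.084 * 332
  bonds <- matrix(FALSE, n, n)  # bonds[d, a]: N-H of d bonded to C=O of a
  energies <- list()
  for (dn in seq_len(n)) {
    if (any(is.na(H[dn, ])) || any(is.na(N[dn, ]))) next
    for (ac in seq_len(n)) {
      if (abs(dn - ac) < 2) next
      if (any(is.na(C[ac, ])) || any(is.na(O[ac, ]))) next
      r_on <- sqrt(sum((O[ac, ] - N[dn, ])^2))
      if (r_on > 5.2) next  # bonds beyond this are weaker than the cutoff
      r_ch <- sqrt(sum((C[ac, ] - H[dn, ])^2))
      r_oh <- sqrt(sum((O[ac, ] - H[dn, ])^2))
      r_cn <- sqrt(sum((C[ac, ] - N[dn, ])^2))
      if (min(r_on, r_ch, r_oh, r_cn) < 0.5) { e <- -9.9 } else {
        e <- q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
      }
      if (e < -0.5) {
        bonds[dn, ac] <- TRUE
        energies[[length(energies) + 1]] <-
          data.frame(donor = rt$key[dn], acceptor = rt$key[ac], energy = e)
      }
    }
  }
  # n-turns: turn_n[i] when donor i+n -> acceptor i, with no chain break inside
  turn <- function(off) {
    t <- rep(FALSE, n)
    for (i in seq_len(n - off)) {
      if (bonds[i + off, i] && !any(brk[(i + 1):(i + off)])) t[i] <- TRUE
    }
    t
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
  codes <- rep("-", n)
  mark <- function(codes, t, off, code) {
    for (i in 2:max(2, n - off)) {
      if (i > n - off) break
      if (t[i - 1] && t[i]) {
        span <- i:(i + off - 1)
        free <- codes[span] == "-" | codes[span] == "T" | codes[span] == code
        if (all(free)) codes[span] <- code
      }
    }
    codes
  }
  if (n >= 5) codes <- mark(codes, t4, 4, "H")   # alpha first (DSSP 3.x)
  if (n >= 4) codes <- mark(codes, t3, 3, "G")
  if (n >= 6) codes <- mark(codes, t5, 5, "I")
  # isolated turns
  for (off in c(3, 4, 5)) {
    t <- switch(as.character(off), "3" = t3, "4" = t4, "5" = t5)
    for (i in which(t)) {
      span <- (i + 1):min(i + off - 1, n)
      codes[span][codes[span] == "-"] <- "T"
    }
  }
  hb <- if (length(energies)) do.call(rbind, energies)
        else data.frame(donor = character(), acceptor = character(),
                        energy = numeric())
  structure(list(codes = setNames(codes, rt$key), hbonds = hb),
            class = "SecStructAssignment")
}

#' @export
print.SecStructAssignment <- function(x, ...) {
  tab <- table(factor(x$codes, levels = c("H", "G", "I", "T", "-")))
  cat("SecStructAssignment:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Longest consecutive pi-helix run in a window
#'
#' Because a pi assignment needs two consecutive i -> i+5 turns, any nonzero
#' run length is at least 5.
#'
#' @param assignment SecStructAssignment.
#' @param window optional `c(resno_min, resno_max)` restricting to author
#'   residue numbers (all chains); `NULL` = whole assignment.
#' @return integer: longest `I` run (0 if none).
#' @export
max_consecutive_pi <- function(assignment, window = NULL) {
  codes <- assignment$codes
  if (!is.null(window)) {
    resno <- as.integer(sub("^[^:]*:(-?[0-9]+):.*$", "\\1", names(codes)))
    codes <- codes[resno >= window[1] & resno <= window[2]]
  }
  if (!length(codes)) return(0L)
  r <- rle(codes == "I")
  if (!any(r$values)) return(0L)
  max(r$lengths[r$values])
}

#' Correlation between pi-helix run length and pore radius
#'
#' Pearson correlation over structures between the longest consecutive
#' S6 pi run and the S6 minimum pore radius.
#'
#' @param records data.frame (or list coercible) with columns `pi_len` and
#'   `min_radius`.
#' @return list with `r` (Pearson coefficient) and `n`.
#' @export
pi_vs_radius <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("pi_len", "min_radius") %in% names(records)))
  x <- records$pi_len; y <- records$min_radius
  if (length(x) < 3) stop("need at least 3 records")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  list(r = stats::cor(x, y), n = length(x))
}

#' Per-residue secondary-structure TSV
#' @param assignment SecStructAssignment.
#' @param path output path.
#' @param structure_id label for the first column.
#' @return `path`, invisibly.
#' @export
write_secstruct_tsv <- function(assignment, path, structure_id = "model") {
  keys <- names(assignment$codes)
  parts <- do.call(rbind, strsplit(keys, ":"))
  tab <- data.frame(structure = structure_id, chain = parts[, 1],
                    resno = parts[, 2], code = unname(assignment$codes))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
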