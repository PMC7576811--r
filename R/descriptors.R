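# covalent-radius corrections alpha_i = r_i / r(C sp3) - 1 for the element
# coverage of the study (CHNO + F). Aromatic carbons take the sp2 value;
# aromatic heteroatoms without an exocyclic double bond (furan O, pyrrole N)
# take their sp3 value.
.alpha_table <- c(
  "C.sp3" = 0.00, "C.sp2" = -0.13, "C.sp" = -0.22,
  "N.sp3" = -0.04, "N.sp2" = -0.20, "N.sp" = -0.29,
  "O.sp3" = -0.04, "O.sp2" = -0.20,
  "F.sp3" = -0.07, "F.sp2" = -0.07, "F.sp" = -0.07
)

# per-atom alpha; aromatic heteroatoms fall back to sp3 unless they carry a
# non-aromatic double bond
.atom_alpha <- function(g) {
  el <- g$atoms$element
  hyb <- g$atoms$hybridization
  n <- nrow(g$atoms)
  arom <- rep(FALSE, n)
  dbl <- rep(FALSE, n)
  for (k in seq_len(nrow(g$bonds))) {
    idx <- c(g$bonds$i[k], g$bonds$j[k])
    if (g$bonds$order[k] == 4L) arom[idx] <- TRUE
    if (g$bonds$order[k] == 2L) dbl[idx] <- TRUE
  }
  eff <- hyb
  het_arom <- arom & el != "C" & !dbl
  eff[het_arom] <- "sp3"
  key <- paste(el, eff, sep = ".")
  a <- .alpha_table[key]
  if (any(is.na(a)))
    stop("no covalent-radius correction for atom type(s): ",
         paste(unique(key[is.na(a)]), collapse = ", "), call. = FALSE)
  unname(a)
}

#' Rotatable bond number (RBN)
#'
#' Counts bonds around which rotation is essentially free: single bonds
#' that are not in a ring, not amide bonds, and not terminal (both
#' endpoints must have heavy-atom degree >= 2, since rotating a terminal
#' bond generates no new conformer).
#'
#' @param g an [molecule_graph()] object.
#' @return Non-negative integer count.
#' @examples
#' g <- molecule_graph(rep("C", 4), cbind(i = 1:3, j = 2:4, order = 1))
#' rotatable_bond_count(g)  # n-butane: the central C-C bond only
#' @export
rotatable_bond_count <- function(g) {
  stopifnot(inherits(g, "eims_molgraph"))
  b <- g$bonds
  if (nrow(b) == 0L) return(0L)
  deg <- g$atoms$degree
  sum(b$order == 1L & !b$in_ring & !b$amide &
        deg[b$i] >= 2L & deg[b$j] >= 2L)
}

#' Alpha-modified Kier kappa shape indices and flexibility index
#'
#' Computes, from a hydrogen-suppressed graph with A heavy atoms, P1 bonds
#' and P2 two-bond paths, the alpha-modified first- and second-order kappa
#' shape indices
#' \deqn{^1\kappa_\alpha = \frac{(A+\alpha)(A+\alpha-1)^2}{(P_1+\alpha)^2},
#'   \quad
#'   ^2\kappa_\alpha = \frac{(A+\alpha-1)(A+\alpha-2)^2}{(P_2+\alpha)^2}}
#' where \eqn{\alpha} sums per-atom covalent-radius corrections relative to
#' sp3 carbon, and the Kier flexibility index
#' \deqn{\Phi = {}^1\kappa_\alpha \cdot {}^2\kappa_\alpha / A.}
#' For a linear all-sp3 carbon chain this collapses to \eqn{\Phi = A - 1};
#' rings and branches lower it. Requires A >= 3 (P2 must be positive).
#'
#' @param g an [molecule_graph()] object with at least 3 atoms.
#' @return `kappa_indices()`: object of class `eims_kappa` — list with
#'   `A`, `P1`, `P2`, `alpha`, `kappa1_alpha`, `kappa2_alpha`, `phi`.
#' @examples
#' hexane <- molecule_graph(rep("C", 6), cbind(i = 1:5, j = 2:6, order = 1))
#' kappa_indices(hexane)$phi  # 5: linear chain closed form A - 1
#' @export
kappa_indices <- function(g) {
  stopifnot(inherits(g, "eims_molgraph"))
  A <- nrow(g$atoms)
  if (A < 3L)
    stop("flexibility index undefined for fewer than 3 heavy atoms",
         call. = FALSE)
  P1 <- nrow(g$bonds)
  deg <- g$atoms$degree
  P2 <- sum(deg * (deg - 1L)) / 2
  alpha <- sum(.atom_alpha(g))
  if (P1 + alpha <= 0 || P2 + alpha <= 0)
    stop("degenerate graph: path count plus alpha is non-positive",
         call. = FALSE)
  k1 <- (A + alpha) * (A + alpha - 1)^2 / (P1 + alpha)^2
  k2 <- (A + alpha - 1) * (A + alpha - 2)^2 / (P2 + alpha)^2
  structure(list(A = A, P1 = P1, P2 = P2, alpha = alpha,
                 kappa1_alpha = k1, kappa2_alpha = k2,
                 phi = k1 * k2 / A),
            class = "eims_kappa")
}

#' @export
print.eims_kappa <- function(x, ...) {
  cat(sprintf(
    "Kappa shape indices: A=%d P1=%d P2=%g alpha=%.2f\n  1k_a=%.4f  2k_a=%.4f  PHI=%.2f\n",
    x$A, x$P1, x$P2, x$alpha, x$kappa1_alpha, x$kappa2_alpha, x$phi))
  invisible(x)
}

#' @rdname kappa_indices
#' @param digits decimals for the reported value (full precision is kept in
#'   [kappa_indices()]).
#' @return `kier_phi()`: the flexibility index rounded for reporting.
#' @export
kier_phi <- function(g, digits = 2) {
  round(kappa_indices(g)$phi, digits)
}
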