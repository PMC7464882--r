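#' Construct a sequential binary partition
#'
#' A sequential binary partition (SBP) encodes D-1 orthonormal balances over
#' the D = 12 composition parts. Each row is a contrast: +1 marks numerator
#' parts, -1 denominator parts, 0 parts not involved. Each contrast must
#' split exactly the parts passed down from its parent, which guarantees the
#' orthogonality of the resulting balance (ilr) basis.
#'
#' @param signs An 11-by-12 matrix of values in \{-1, 0, +1\}, columns in the
#'   canonical part order.
#' @return An object of class `sbp` (the validated sign matrix, with the
#'   orthonormal contrast matrix in attribute `psi`).
#' @seealso [build_default_sbp()], [ilr_transform()]
#' @export
sbp_matrix <- function(signs) {
  signs <- as.matrix(signs)
  if (ncol(signs) != 12 || nrow(signs) != 11) {
    stop("SBP must have 11 contrasts over 12 parts")
  }
  if (!all(signs %in% c(-1, 0, 1))) stop("SBP entries must be -1, 0 or +1")
  colnames(signs) <- composition_parts()
  psi <- matrix(0, 11, 12, dimnames = list(rownames(signs), colnames(signs)))
  for (i in seq_len(11)) {
    r <- sum(signs[i, ] == 1)
    s <- sum(signs[i, ] == -1)
    if (r == 0 || s == 0) stop("each contrast needs numerator and denominator parts")
    coefr <- sqrt(r * s / (r + s))
    psi[i, signs[i, ] == 1] <- coefr / r
    psi[i, signs[i, ] == -1] <- -coefr / s
  }
  gram <- psi %*% t(psi)
  if (max(abs(gram - diag(11))) > 1e-10) {
    stop("SBP contrasts are not orthonormal; check the partition hierarchy")
  }
  structure(signs, psi = psi, class = "sbp")
}

#' Default sequential binary partition
#'
#' A fixed, interpretable partition of the 12 parts: the quantified nutrients
#' are first contrasted against the filling value, then macronutrients
#' against micronutrients, followed by cascading bisections within each
#' group. The coefficient of contrast i is \eqn{\sqrt{rs/(r+s)}}, with r and
#' s the numerator and denominator part counts.
#'
#' Contrast order: `[nutrients | Fv]`, `[macro | micro]`,
#' `[N,P,K | Mg,Ca,S]`, `[N,P | K]`, `[N | P]`, `[Mg,Ca | S]`, `[Mg | Ca]`,
#' `[B,Cu,Zn | Mn,Fe]`, `[B,Cu | Zn]`, `[B | Cu]`, `[Mn | Fe]`.
#'
#' All distances and multivariate results are invariant to the particular
#' partition chosen (see [aitchison_distance()]).
#'
#' @return An `sbp` object.
#' @export
build_default_sbp <- function() {
  contrasts <- list(
    nutrients_vs_Fv = list(num = nutrient_parts(), den = "Fv"),
    macro_vs_micro  = list(num = c("N", "P", "K", "Mg", "Ca", "S"),
                           den = c("B", "Cu", "Zn", "Mn", "Fe")),
    NPK_vs_MgCaS    = list(num = c("N", "P", "K"), den = c("Mg", "Ca", "S")),
    NP_vs_K         = list(num = c("N", "P"), den = "K"),
    N_vs_P          = list(num = "N", den = "P"),
    MgCa_vs_S       = list(num = c("Mg", "Ca"), den = "S"),
    Mg_vs_Ca        = list(num = "Mg", den = "Ca"),
    BCuZn_vs_MnFe   = list(num = c("B", "Cu", "Zn"), den = c("Mn", "Fe")),
    BCu_vs_Zn       = list(num = c("B", "Cu"), den = "Zn"),
    B_vs_Cu         = list(num = "B", den = "Cu"),
    Mn_vs_Fe        = list(num = "Mn", den = "Fe")
  )
  signs <- matrix(0, 11, 12,
                  dimnames = list(names(contrasts), composition_parts()))
  for (i in seq_along(contrasts)) {
    signs[i, contrasts[[i]]$num] <- 1
    signs[i, contrasts[[i]]$den] <- -1
  }
  sbp_matrix(signs)
}

# alternative partition (each part against all later parts); used to verify
# that results do not depend on the chosen SBP
build_sequential_sbp <- function() {
  parts <- composition_parts()
  signs <- matrix(0, 11, 12,
                  dimnames = list(paste0(parts[1:11], "_vs_rest"), parts))
  for (i in seq_len(11)) {
    signs[i, i] <- 1
    signs[i, (i + 1):12] <- -1
  }
  sbp_matrix(signs)
}

#' Isometric log-ratio (balance) transform
#'
#' Computes the 11 orthonormal balances
#' \eqn{ilr_i = \sqrt{rs/(r+s)}\,\ln(G_N/G_D)} defined by a sequential binary
#' partition, where \eqn{G_N} and \eqn{G_D} are the geometric means of the
#' numerator and denominator parts. The ilr coordinates are an isometric
#' image of clr space: Euclidean distances are identical in either
#' representation and do not depend on the partition.
#'
#' @param x A `composition` or n-by-12 matrix of compositions.
#' @param sbp An `sbp` object (default [build_default_sbp()]).
#' @return Numeric vector of 11 balances (or n-by-11 matrix), named after the
#'   SBP contrasts.
#' @export
ilr_transform <- function(x, sbp = build_default_sbp()) {
  if (!inherits(sbp, "sbp")) stop("sbp must be an 'sbp' object")
  psi <- attr(sbp, "psi")
  if (is.matrix(x)) {
    if (any(x <= 0)) stop("non-positive part")
    return(log(x) %*% t(psi))
  }
  v <- as.numeric(x)
  if (length(v) != 12) stop("composition must have 12 parts")
  if (any(v <= 0)) stop("non-positive part")
  drop(psi %*% log(v))
}
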