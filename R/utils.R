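# Small shared helpers: rigid-body fitting, distances, validation.

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' matched coordinate sets. The rotation is constrained to determinant +1
#' (no reflection).
#'
#' @param mobile n x 3 matrix moved onto `fixed`.
#' @param fixed n x 3 matrix of target coordinates.
#' @return list with `rotation` (3 x 3), `translation` (length 3) such that
#'   `sweep(mobile %*% t(rotation), 2, translation, "+")` superposes onto
#'   `fixed`, and the resulting `rmsd`.
#' @export
kabsch <- function(mobile, fixed) {
  stopifnot(is.matrix(mobile), is.matrix(fixed),
            nrow(mobile) == nrow(fixed), ncol(mobile) == 3, ncol(fixed) == 3)
  if (nrow(mobile) < 3) stop("need at least 3 matched points for superposition")
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  a <- sweep(mobile, 2, cm); b <- sweep(fixed, 2, cf)
  h <- crossprod(a, b)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # maps mobile-frame -> fixed-frame
  rot <- t(rot)                                  # so that mobile %*% t(rot) ... store as x %*% rotation
  moved <- a %*% rot
  rmsd <- sqrt(mean(rowSums((moved - b)^2)))
  list(rotation = rot, translation = as.numeric(cf - cm %*% rot), rmsd = rmsd)
}

#' Apply a superposition to coordinates
#' @param xyz n x 3 matrix.
#' @param fit result of [kabsch()].
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(xyz, fit) {
  sweep(xyz %*% fit$rotation, 2, fit$translation, "+")
}

rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Pairwise Euclidean distances between rows of a and rows of b.
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Known one- and two-letter element symbols (upper case) for validation.
.elements <- c(
  "H", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE", "NA", "MG", "AL",
  "SI", "P", "S", "CL", "AR", "K", "CA", "SC", "TI", "V", "CR", "MN", "FE",
  "CO", "NI", "CU", "ZN", "GA", "GE", "AS", "SE", "BR", "KR", "RB", "SR",
  "Y", "ZR", "NB", "MO", "RU", "RH", "PD", "AG", "CD", "IN", "SN", "SB",
  "TE", "I", "XE", "CS", "BA", "LA", "CE", "PR", "ND", "SM", "EU", "GD",
  "TB", "DY", "HO", "ER", "TM", "YB", "LU", "HF", "TA", "W", "RE", "OS",
  "IR", "PT", "AU", "HG", "TL", "PB", "BI", "U")

valid_element <- function(x) toupper(x) %in% .elements

# Infer an element symbol from a PDB atom name when the element column is
# absent. Names starting with a digit are hydrogens ("1HB"); otherwise the
# leading alphabetic characters are matched against two-letter symbols first
# (metals such as FE, ZN), falling back to the first letter.
infer_element <- function(atom_name, is_hetero = FALSE) {
  nm <- toupper(gsub("[^A-Za-z0-9]", "", atom_name))
  if (grepl("^[0-9]", nm)) return("H")
  alpha <- gsub("[0-9]", "", nm)
  two <- substr(alpha, 1, 2)
  one <- substr(alpha, 1, 1)
  # Two-letter matches are only trusted for hetero atoms or unambiguous
  # metals: polymer atom names like "CA"/"CD" are carbon, not calcium.
  if (nchar(alpha) >= 2 && two %in% .elements &&
      (is_hetero || !one %in% c("C", "N", "O", "S", "P", "H"))) {
    return(two)
  }
  if (one %in% .elements) return(one)
  stop("cannot infer element from atom name '", atom_name, "'")
}
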