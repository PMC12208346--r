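#' @keywords internal
"_PACKAGE"

# Canonical part order used throughout: wake in bed, light sleep,
# slow-wave sleep, REM sleep.
SLEEP_PARTS <- c("twt", "light", "sws", "rem")

#' Canonical sleep-stage part names
#'
#' Returns the fixed order of the four sleep-architecture parts used by every
#' function in the package: total wake time in bed (`twt`), light sleep
#' (`light`, NREM 1+2), slow-wave sleep (`sws`, NREM 3) and REM sleep (`rem`).
#'
#' @return Character vector of length 4.
#' @export
sleep_parts <- function() SLEEP_PARTS

#' Close a composition to a fixed total
#'
#' Rescales a vector (or rows of a matrix) of non-negative parts so that it
#' sums to `total`, preserving all ratios between parts.
#'
#' @param x Numeric vector of non-negative parts, or a matrix with one
#'   composition per row.
#' @param total Positive scalar the output must sum to (default 1).
#' @return Object of the same shape as `x`, each composition summing to
#'   `total`.
#' @examples
#' close_comp(c(71.77, 190.78, 86.58, 98.35))
#' @export
close_comp <- function(x, total = 1) {
  stopifnot(is.numeric(x), length(total) == 1L, is.finite(total), total > 0)
  if (is.matrix(x)) {
    if (any(x < 0) || any(!is.finite(x))) {
      stop("parts must be finite and non-negative")
    }
    s <- rowSums(x)
    if (any(s <= 0)) stop("degenerate composition: all parts zero")
    return(x / s * total)
  }
  if (any(x < 0) || any(!is.finite(x))) stop("parts must be finite and non-negative")
  s <- sum(x)
  if (s <= 0) stop("degenerate composition: all parts zero")
  x / s * total
}

#' Geometric-mean composition
#'
#' Closed per-part geometric mean of a set of compositions: the compositional
#' centre. Equals the inverse ilr transform of the arithmetic mean of the ilr
#' coordinates for any orthonormal basis.
#'
#' @param x Matrix with one strictly positive composition per row.
#' @param total Closure total of the result (default 1).
#' @return Numeric vector: the closed geometric-mean composition.
#' @export
gmean_comp <- function(x, total = 1) {
  x <- rbind(x)
  if (nrow(x) < 1L) stop("need at least one composition")
  if (any(x <= 0)) {
    stop("all parts must be strictly positive; call replace_zeros() first")
  }
  close_comp(exp(colMeans(log(x))), total)
}

#' Default sequential binary partition for the four sleep stages
#'
#' Three ordered binary splits defining the package's default ilr coordinate
#' system: (1) wake in bed vs all sleep, (2) light sleep vs deep sleep
#' (SWS + REM), (3) SWS vs REM. Downstream substitution estimates are
#' invariant to this choice; it only fixes which balances are reported.
#'
#' @return Integer matrix with 3 rows and one column per part, entries in
#'   \{-1, 0, 1\}.
#' @export
default_sbp <- function() {
  sbp <- rbind(
    c(1, -1, -1, -1),
    c(0,  1, -1, -1),
    c(0,  0,  1, -1)
  )
  colnames(sbp) <- SLEEP_PARTS
  rownames(sbp) <- c("wake.vs.sleep", "light.vs.deep", "sws.vs.rem")
  sbp
}

# Check that sign rows form a laminar binary-partition hierarchy that fully
# resolves the parts. Rows may appear in any order; supports must be nested
# or disjoint, each non-root support must coincide with one side of its
# minimal strict superset, and splits must end in singletons.
validate_sbp <- function(sbp) {
  sbp <- rbind(sbp)
  D <- ncol(sbp)
  if (nrow(sbp) != D - 1L) {
    stop("a sequential binary partition of ", D, " parts needs ", D - 1L, " rows")
  }
  if (!all(sbp %in% c(-1L, 0L, 1L))) stop("SBP entries must be -1, 0 or 1")
  supports <- lapply(seq_len(nrow(sbp)), function(i) which(sbp[i, ] != 0))
  for (i in seq_len(nrow(sbp))) {
    if (!any(sbp[i, ] > 0) || !any(sbp[i, ] < 0)) {
      stop("SBP row ", i, " must have at least one +1 and one -1")
    }
  }
  sizes <- lengths(supports)
  root <- which(sizes == D)
  if (length(root) != 1L) stop("invalid SBP: exactly one row must involve all parts")
  for (i in seq_len(nrow(sbp))) {
    for (j in seq_len(nrow(sbp))) {
      if (i == j) next
      inter <- intersect(supports[[i]], supports[[j]])
      if (length(inter) &&
          length(inter) != length(supports[[i]]) &&
          length(inter) != length(supports[[j]])) {
        stop("invalid SBP: rows ", i, " and ", j, " overlap without nesting")
      }
    }
  }
  for (i in seq_len(nrow(sbp))) {
    if (sizes[i] == D) next
    parents <- which(vapply(seq_len(nrow(sbp)), function(j) {
      sizes[j] > sizes[i] && all(supports[[i]] %in% supports[[j]])
    }, logical(1)))
    if (!length(parents)) stop("invalid SBP: row ", i, " has no parent split")
    parent <- parents[which.min(sizes[parents])]
    pos <- which(sbp[parent, ] > 0)
    neg <- which(sbp[parent, ] < 0)
    if (!(setequal(supports[[i]], pos) || setequal(supports[[i]], neg))) {
      stop("invalid SBP: row ", i, " does not split one side of row ", parent)
    }
  }
  # every group of size > 1 produced by a split must itself be split
  for (i in seq_len(nrow(sbp))) {
    for (side in list(which(sbp[i, ] > 0), which(sbp[i, ] < 0))) {
      if (length(side) > 1L &&
          !any(vapply(supports, function(s) setequal(s, side), logical(1)))) {
        stop("invalid SBP: the parts ", paste(side, collapse = ","),
             " are never resolved")
      }
    }
  }
  invisible(sbp)
}

#' Build an orthonormal ilr basis from a sequential binary partition
#'
#' Each SBP row with `r` positive and `s` negative parts yields one balance
#' coordinate with contrast coefficients `+sqrt(s / (r * (r + s)))` on the
#' positive parts and `-sqrt(r / (s * (r + s)))` on the negative parts. The
#' resulting (D-1) x D matrix `V` satisfies `V %*% t(V) == I` and has
#' zero-sum rows.
#'
#' @param sbp Sign matrix as returned by [default_sbp()]; one row per split,
#'   entries in \{-1, 0, 1\}.
#' @param parts Character vector naming the columns (defaults to the column
#'   names of `sbp`, else [sleep_parts()] when there are four columns).
#' @return An object of class `ilr_basis`: list with elements `contrast`
#'   (the matrix V), `parts`, and `sbp`.
#' @examples
#' basis <- build_ilr_basis(default_sbp())
#' basis$contrast %*% t(basis$contrast)  # identity
#' @export
build_ilr_basis <- function(sbp, parts = NULL) {
  sbp <- validate_sbp(sbp)
  D <- ncol(sbp)
  if (is.null(parts)) {
    parts <- colnames(sbp)
    if (is.null(parts)) {
      parts <- if (D == length(SLEEP_PARTS)) SLEEP_PARTS else paste0("part", seq_len(D))
    }
  }
  stopifnot(length(parts) == D)
  V <- matrix(0, nrow(sbp), D, dimnames = list(rownames(sbp), parts))
  for (i in seq_len(nrow(sbp))) {
    r <- sum(sbp[i, ] > 0)
    s <- sum(sbp[i, ] < 0)
    V[i, sbp[i, ] > 0] <- sqrt(s / (r * (r + s)))
    V[i, sbp[i, ] < 0] <- -sqrt(r / (s * (r + s)))
  }
  structure(list(contrast = V, parts = parts, sbp = sbp), class = "ilr_basis")
}

#' @export
print.ilr_basis <- function(x, ...) {
  cat("ilr basis over parts:", paste(x$parts, collapse = ", "), "\n")
  print(round(x$contrast, 4))
  invisible(x)
}

as_ilr_basis <- function(basis) {
  if (inherits(basis, "ilr_basis")) return(basis)
  if (is.matrix(basis)) return(build_ilr_basis(basis))
  stop("`basis` must be an ilr_basis or an SBP sign matrix")
}

#' Isometric log-ratio transform
#'
#' Maps strictly positive compositions to D-1 unconstrained balance
#' coordinates: `z = V %*% log(close(x, 1))`. The map is scale invariant in
#' the input total and an isometry between Aitchison and Euclidean geometry.
#'
#' @param x Positive composition vector, or matrix with one composition per
#'   row.
#' @param basis An `ilr_basis` (default: basis of [default_sbp()]).
#' @return Numeric vector of length D-1, or an n x (D-1) matrix.
#' @export
ilr_transform <- function(x, basis = build_ilr_basis(default_sbp())) {
  basis <- as_ilr_basis(basis)
  vec <- !is.matrix(x)
  x <- rbind(x)
  if (ncol(x) != ncol(basis$contrast)) {
    stop("composition has ", ncol(x), " parts; basis expects ", ncol(basis$contrast))
  }
  if (any(x <= 0) || any(!is.finite(x))) {
    stop("ilr requires strictly positive, finite parts; see replace_zeros()")
  }
  lx <- log(x / rowSums(x))
  z <- lx %*% t(basis$contrast)
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  if (vec) drop(z) else z
}

#' Inverse isometric log-ratio transform
#'
#' Maps balance coordinates back to the simplex: `close(exp(t(V) %*% z), 1)`.
#' Computed with a log-sum-exp guard so large-magnitude coordinates cannot
#' overflow.
#'
#' @param z Numeric vector of length D-1, or matrix with one coordinate row
#'   per observation.
#' @param basis An `ilr_basis`.
#' @param total Closure total of the returned composition (default 1; pass
#'   time in bed to obtain minutes).
#' @return Composition vector or matrix closed to `total`.
#' @export
ilr_inverse <- function(z, basis = build_ilr_basis(default_sbp()), total = 1) {
  basis <- as_ilr_basis(basis)
  vec <- !is.matrix(z)
  z <- rbind(z)
  if (any(!is.finite(z))) stop("ilr coordinates must be finite")
  if (ncol(z) != nrow(basis$contrast)) {
    stop("coordinate vector has ", ncol(z), " entries; basis expects ",
         nrow(basis$contrast))
  }
  lx <- z %*% basis$contrast
  lx <- lx - apply(lx, 1L, max)          # log-sum-exp guard
  x <- exp(lx)
  x <- x / rowSums(x) * total
  colnames(x) <- basis$parts
  if (vec) drop(x) else x
}

#' Multiplicative zero replacement
#'
#' Replaces zero parts with a small positive duration `delta` and rescales
#' the non-zero parts multiplicatively so the composition total is preserved
#' exactly and the ratios among observed (non-zero) parts are unchanged.
#'
#' @param x Non-negative composition in the same units as `total` (minutes).
#' @param total Positive total the composition sums to; defaults to `sum(x)`.
#' @param delta Replacement value for each zero part, in minutes
#'   (default 0.5, half a 1-minute scoring epoch).
#' @return Strictly positive composition summing to `total`.
#' @examples
#' replace_zeros(c(0, 300, 100, 50), delta = 0.5)
#' @export
replace_zeros <- function(x, total = sum(x), delta = 0.5) {
  stopifnot(is.numeric(x), all(x >= 0), total > 0, delta > 0)
  nz <- sum(x == 0)
  if (nz == 0L) return(close_comp(x, total))
  if (delta * nz >= total) {
    stop("delta too large: ", nz, " zero parts at ", delta,
         " min exceed the total of ", total, " min")
  }
  out <- x
  out[x == 0] <- delta
  out[x > 0] <- x[x > 0] * (total - delta * nz) / sum(x[x > 0])
  # preserve units: result sums to `total` by construction
  out
}
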