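#' Declare a complex sampling design
#'
#' Bundles a data frame with the three design columns that drive
#' design-based (Taylor-linearized) variance estimation: per-row sampling
#' weights, sampling strata, and primary sampling units (PSUs) nested in
#' strata.  Variance estimation treats PSUs as sampled with replacement
#' within strata, the usual approximation for public-release NHANES-style
#' designs.
#'
#' @param data data frame holding the analysis variables and the design
#'   columns.
#' @param weights name of the column of strictly positive sampling weights,
#'   or `NULL` for equal weights.
#' @param strata name of the stratum identifier column, or `NULL` for a
#'   single stratum.
#' @param ids name of the PSU identifier column, or `NULL` to treat every
#'   row as its own PSU (no clustering).
#'
#' @return An object of class `svy_design`: a list with elements `data`,
#'   `weights` (numeric vector), `strata` (factor), `psu` (factor,
#'   stratum-crossed), and `call`.
#' @examples
#' d <- data.frame(y = rbinom(20, 1, 0.4), x = rnorm(20),
#'                 w = runif(20, 1, 3),
#'                 st = rep(1:2, each = 10), cl = rep(1:4, each = 5))
#' des <- svy_design(d, weights = "w", strata = "st", ids = "cl")
#' des
#' @export
svy_design <- function(data, weights = NULL, strata = NULL, ids = NULL) {
  stopifnot(is.data.frame(data))
  n <- nrow(data)
  get_col <- function(nm, what) {
    if (is.null(nm)) return(NULL)
    if (!is.character(nm) || length(nm) != 1L || !nm %in% names(data))
      stop(sprintf("%s column '%s' not found in data", what,
                   paste(nm, collapse = ",")), call. = FALSE)
    data[[nm]]
  }
  w <- get_col(weights, "weights")
  if (is.null(w)) w <- rep(1, n)
  if (!is.numeric(w) || anyNA(w) || any(w <= 0))
    stop("sampling weights must be strictly positive and non-missing",
         call. = FALSE)
  st <- get_col(strata, "strata")
  if (is.null(st)) st <- rep(1L, n)
  cl <- get_col(ids, "ids")
  if (is.null(cl)) cl <- seq_len(n)
  st <- factor(st)
  # PSU ids only need to be unique within stratum; cross with stratum so
  # identical labels in different strata stay distinct clusters
  psu <- factor(paste(as.integer(st), cl, sep = "."))
  structure(
    list(data = data, weights = w, strata = st, psu = psu,
         call = match.call()),
    class = "svy_design")
}

#' @export
print.svy_design <- function(x, ...) {
  cat("Complex survey design (with-replacement PSU approximation)\n")
  cat(sprintf("  %d observations, %d strata, %d PSUs\n",
              length(x$weights), nlevels(droplevels(x$strata)),
              nlevels(droplevels(x$psu))))
  cat(sprintf("  weight range: [%g, %g]\n",
              min(x$weights), max(x$weights)))
  invisible(x)
}

#' Subset a survey design
#'
#' Restricts a [svy_design()] to a set of rows (domain analysis).  Strata
#' and PSU labels are retained so that variance estimation still reflects
#' the full design's clustering.
#'
#' @param design a `svy_design` object.
#' @param idx logical or integer row index.
#' @return A `svy_design` on the selected rows.
#' @export
subset_design <- function(design, idx) {
  stopifnot(inherits(design, "svy_design"))
  if (is.logical(idx)) idx[is.na(idx)] <- FALSE
  structure(
    list(data = design$data[idx, , drop = FALSE],
         weights = design$weights[idx],
         strata = droplevels(design$strata[idx]),
         psu = droplevels(design$psu[idx]),
         call = design$call),
    class = "svy_design")
}

#' @export
dim.svy_design <- function(x) dim(x$data)

# Taylor-linearization variance of a total of estimating-function
# contributions.  `scores` is an n x p matrix of weighted per-observation
# contributions; clusters are summed to PSU totals z_hj and
# V = sum_h n_h/(n_h-1) sum_j (z_hj - zbar_h)(z_hj - zbar_h)'.
# Strata with a single PSU either error or are centered at the grand mean
# of PSU totals (single_psu = "center").
taylor_linearized_vcov <- function(scores, strata, psu,
                                   single_psu = c("fail", "center")) {
  single_psu <- match.arg(single_psu)
  scores <- as.matrix(scores)
  p <- ncol(scores)
  strata <- droplevels(factor(strata))
  psu <- droplevels(factor(psu))
  # PSU totals
  z <- rowsum(scores, group = psu, reorder = FALSE)
  psu_stratum <- strata[match(rownames(z), as.character(psu))]
  V <- matrix(0, p, p)
  nh <- table(psu_stratum)
  if (any(nh == 1L)) {
    if (single_psu == "fail")
      stop("stratum with a single PSU: design-based variance undefined ",
           "(use single_psu = \"center\" to center lonely PSUs at the ",
           "grand mean)", call. = FALSE)
    gm <- colMeans(z)
  }
  for (h in levels(psu_stratum)) {
    zh <- z[psu_stratum == h, , drop = FALSE]
    m <- nrow(zh)
    if (m == 1L) {
      d <- sweep(zh, 2, gm)
      V <- V + crossprod(d)
    } else {
      d <- sweep(zh, 2, colMeans(zh))
      V <- V + m / (m - 1) * crossprod(d)
    }
  }
  (V + t(V)) / 2
}

# design degrees of freedom: number of PSUs minus number of strata
design_df <- function(design) {
  nlevels(droplevels(design$psu)) - nlevels(droplevels(design$strata))
}
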