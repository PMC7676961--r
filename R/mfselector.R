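# DEtotal internals ----------------------------------------------------------
#
# All split errors are computed on a once-sorted copy of the gene's values:
# for a candidate line t placed at the end of a tie block (sorted position j),
# the misclassified count for "first k stages below, rest above" is
#   (#lower-group samples with value > t) + (#upper-group samples <= t)
#   = n_low - cum[j] + (j - cum[j])
# with cum the cumsum of lower-group membership in sorted order. Only tie
# block ends need to be scanned, so one split costs O(n) after the sort.

#' @noRd
.mf_prep <- function(values) {
  ord <- order(values)
  vs <- values[ord]
  n <- length(vs)
  list(ord = ord, vs = vs, n = n,
       blocks = which(c(vs[-n] < vs[-1], TRUE)))
}

#' @noRd
.mf_split <- function(prep, low) {
  low <- low[prep$ord]
  cum <- cumsum(low)
  n_low <- cum[prep$n]
  # leading entry: the sentinel line below all observations (misclassifies
  # exactly the lower side), so a split never costs more than one full side
  mis <- c(n_low, n_low + prep$blocks - 2L * cum[prep$blocks])
  j <- which.min(mis)  # first minimum = smallest line on ties
  list(misclassified = as.integer(mis[j]),
       line = if (j == 1L) -Inf else prep$vs[prep$blocks[j - 1L]])
}

#' @noRd
.mf_detotal_stat <- function(prep, stage_idx, K) {
  si <- stage_idx[prep$ord]
  total <- 0L
  for (k in seq_len(K - 1L)) {
    low <- si <= k
    cum <- cumsum(low)
    n_low <- cum[prep$n]
    total <- total +
      min(n_low, min(n_low + prep$blocks - 2L * cum[prep$blocks]))
  }
  total
}

#' @noRd
.stage_index <- function(stages) {
  stages <- as.integer(stages)
  lev <- sort(unique(stages))
  if (length(lev) < 2) stop("at least 2 stages are required")
  list(idx = match(stages, lev), K = length(lev))
}

#' Minimum misclassification of one cumulative stage split
#'
#' For split `k`, a discriminating line (threshold on this gene's
#' expression) separates the first `k` stage groups from the rest. Under
#' `direction = "increasing"` the lower groups are expected below the line:
#' a lower-group sample strictly above the line or an upper-group sample at
#' or below it is misclassified (a sample exactly at the line counts as
#' below). Candidate lines are placed at every observed value, plus one
#' sentinel line below all observations (reported as `-Inf`) that concedes
#' the whole lower side, so a split never costs more than the smaller of
#' its two sides; the minimum misclassified count and the smallest
#' minimizing line are returned. The
#' decreasing direction is the exact mirror, computed by negating the
#' values, so its boundary rule and tie-break are mirrored too.
#'
#' @param values Numeric expression values, one per sample.
#' @param stages Ordinal stage codes, one per sample.
#' @param k Split index in `1 .. K-1` (K = number of distinct stages).
#' @param direction `"increasing"` or `"decreasing"`.
#'
#' @return List with `misclassified` (integer) and `line` (numeric).
#' @examples
#' split_error(c(1, 2, 3, 4), c(1, 1, 2, 2), k = 1)  # 0 misclassified
#' @export
split_error <- function(values, stages,
                        k, direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("non-finite expression value")
  s <- .stage_index(stages)
  if (length(values) != length(s$idx)) {
    stop("values and stages must have the same length")
  }
  if (!(k %in% seq_len(s$K - 1L))) {
    stop("k must lie in 1 .. K-1 = 1 .. ", s$K - 1L)
  }
  if (direction == "decreasing") {
    res <- split_error(-values, stages, k, "increasing")
    res$line <- -res$line
    return(res)
  }
  .mf_split(.mf_prep(values), s$idx <= k)
}

#' DEtotal: total discriminating error of one gene
#'
#' Sums the minimum misclassification over the `K-1` cumulative stage
#' splits. A gene has a perfect monotone tendency when every split is
#' separated without error and the `K-1` discriminating lines are strictly
#' ordered in the tested direction (later-stage lines above earlier ones for
#' `"increasing"`). The decreasing direction is computed by negation, so
#' `detotal(v, "decreasing") == detotal(-v, "increasing")` exactly.
#'
#' @inheritParams split_error
#'
#' @return List with `detotal` (integer), `split_errors` (integer, length
#'   K-1), `lines` (numeric, length K-1), `perfect_monotone` (logical) and
#'   `direction`.
#' @export
detotal <- function(values, stages,
                    direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("non-finite expression value")
  s <- .stage_index(stages)
  if (length(values) != length(s$idx)) {
    stop("values and stages must have the same length")
  }
  w <- if (direction == "decreasing") -values else values
  prep <- .mf_prep(w)
  errs <- integer(s$K - 1L)
  lines <- numeric(s$K - 1L)
  for (k in seq_len(s$K - 1L)) {
    sp <- .mf_split(prep, s$idx <= k)
    errs[k] <- sp$misclassified
    lines[k] <- sp$line
  }
  perfect <- sum(errs) == 0L && all(is.finite(lines)) &&
    all(diff(lines) > 0)
  if (direction == "decreasing") lines <- -lines
  list(detotal = sum(errs), split_errors = errs, lines = lines,
       perfect_monotone = perfect, direction = direction)
}

#' @noRd
.multiset_perms <- function(x) {
  n <- length(x)
  if (n <= 1L) return(matrix(x, ncol = 1L))
  out <- list()
  for (u in unique(x)) {
    rest <- .multiset_perms(x[-match(u, x)])
    out[[length(out) + 1L]] <- rbind(rep(u, ncol(rest)), rest)
  }
  do.call(cbind, out)
}

#' Permutation p-value for a gene's DEtotal
#'
#' Stage labels are permuted and DEtotal recomputed each time; small
#' observed scores are evidence of monotone separation, so the p-value is
#' the probability of a permuted score at or below the observed one. The
#' sampled estimator uses the add-one form
#' `p = (1 + #\{DEtotal_perm <= DEtotal_obs\}) / (n_perm + 1)`, which never
#' returns zero. With `exact = TRUE` all distinct label assignments are
#' enumerated instead (feasible only for small cohorts) and the p-value is
#' the exact enumeration fraction.
#'
#' @inheritParams split_error
#' @param n_perm Number of sampled permutations; default 1000.
#' @param seed Integer seed for the label permutations (local to this call).
#' @param exact Enumerate all distinct stage-label assignments instead of
#'   sampling; errors beyond 500000 assignments.
#'
#' @return The permutation p-value in (0, 1].
#' @export
mf_permutation_test <- function(values, stages,
                                direction = c("increasing", "decreasing"),
                                n_perm = 1000, seed = NULL, exact = FALSE) {
  direction <- match.arg(direction)
  values <- as.numeric(values)
  s <- .stage_index(stages)
  w <- if (direction == "decreasing") -values else values
  prep <- .mf_prep(w)
  obs <- .mf_detotal_stat(prep, s$idx, s$K)
  if (exact) {
    n_distinct <- exp(lfactorial(length(s$idx)) -
                        sum(lfactorial(table(s$idx))))
    if (n_distinct > 5e5) {
      stop("too many distinct assignments (", round(n_distinct),
           ") for exact enumeration; use sampling")
    }
    perms <- .multiset_perms(s$idx)
    stats <- apply(perms, 2, function(si) .mf_detotal_stat(prep, si, s$K))
    return(mean(stats <= obs))
  }
  if (!is.numeric(n_perm) || n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) withr::local_seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (.mf_detotal_stat(prep, sample(s$idx), s$K) <= obs) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' MFSelector screen over an expression matrix
#'
#' Per-gene DEtotal with a label-permutation null and multiple-testing
#' adjustment ([adjust_pvalues()], BH by default). By default a single set
#' of label permutations is shared by all genes (one shuffle per
#' permutation round), which preserves between-gene correlation under the
#' null; `per_gene_perms = TRUE` draws independent permutations per gene.
#' `direction = "both"` tests each gene in both directions and keeps the
#' smaller DEtotal (the permuted statistic is minimized the same way).
#'
#' @param expr Numeric genes x samples matrix with dimnames.
#' @param design A [stage_design()] over the columns of `expr`.
#' @param direction `"increasing"`, `"decreasing"` or `"both"`.
#' @param alpha Significance threshold on adjusted p-values.
#' @param n_perm Permutations per gene; default 1000.
#' @param seed Integer seed for the permutation null.
#' @param per_gene_perms Draw independent permutations per gene.
#'
#' @return An `mf_table` data.frame: `gene`, `detotal`, `split_errors`
#'   (semicolon-joined), `perfect_monotone`, `p_perm`, `p_adjusted`,
#'   `significant`, `direction`; attributes `alpha`, `n_perm`.
#' @export
mfselect <- function(expr, design,
                     direction = c("increasing", "decreasing", "both"),
                     alpha = 0.05, n_perm = 1000, seed = 1,
                     per_gene_perms = FALSE) {
  direction <- match.arg(direction)
  stopifnot(inherits(design, "stage_design"))
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expr must have gene rownames and sample colnames")
  }
  if (!setequal(colnames(expr), design$sample) ||
      ncol(expr) != nrow(design)) {
    stop("sample axes of expr and design do not match")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  design <- design[match(colnames(expr), design$sample), , drop = FALSE]
  s <- .stage_index(design$stage)
  n <- ncol(expr)
  p <- nrow(expr)
  dirs <- if (direction == "both") c("increasing", "decreasing")
          else direction

  withr::local_seed(seed)
  perm_shared <- if (!per_gene_perms) {
    lapply(seq_len(n_perm), function(b) sample(n))
  }

  res <- vector("list", p)
  for (i in seq_len(p)) {
    v <- expr[i, ]
    cand <- lapply(dirs, function(dd) detotal(v, design$stage, dd))
    best <- cand[[which.min(vapply(cand, `[[`, 0L, "detotal"))]]
    preps <- lapply(dirs, function(dd) {
      .mf_prep(if (dd == "decreasing") -v else v)
    })
    perms <- if (per_gene_perms) {
      lapply(seq_len(n_perm), function(b) sample(n))
    } else {
      perm_shared
    }
    hits <- 0L
    for (b in seq_len(n_perm)) {
      si <- s$idx[perms[[b]]]
      stat <- min(vapply(preps, .mf_detotal_stat, 0L,
                         stage_idx = si, K = s$K))
      if (stat <= best$detotal) hits <- hits + 1L
    }
    res[[i]] <- data.frame(
      gene = rownames(expr)[i], detotal = best$detotal,
      split_errors = paste(best$split_errors, collapse = ";"),
      perfect_monotone = best$perfect_monotone,
      p_perm = (1 + hits) / (n_perm + 1),
      direction = best$direction, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$p_adjusted <- adjust_pvalues(out$p_perm, "BH")
  out$significant <- out$p_adjusted <= alpha
  out <- out[c("gene", "detotal", "split_errors", "perfect_monotone",
               "p_perm", "p_adjusted", "significant", "direction")]
  attr(out, "alpha") <- alpha
  attr(out, "n_perm") <- n_perm
  class(out) <- c("mf_table", "data.frame")
  out
}
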