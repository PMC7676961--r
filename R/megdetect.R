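#' Per-sample stage design
#'
#' Records the ordinal pathologic stage of each sample. Stage codes are
#' nonnegative integers in progression order; code 0 is reserved for a
#' normal-control group (not all cohorts include one). Display labels (e.g.
#' IA/IB/IIA/IIB mapped to 1..4) are carried along for reporting only — the
#' package never parses Roman numerals itself.
#'
#' @param samples Character vector of unique sample identifiers.
#' @param stage Integer vector of stage codes, one per sample; `>= 0`.
#' @param labels Optional character vector of display names per sample.
#'
#' @return A `stage_design` data.frame with columns `sample`, `stage` and
#'   (optionally) `label`.
#' @examples
#' stage_design(paste0("s", 1:6), c(1, 1, 2, 2, 3, 3))
#' @export
stage_design <- function(samples, stage, labels = NULL) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicated sample identifiers")
  if (length(stage) != length(samples)) {
    stop("'stage' must have one entry per sample")
  }
  if (any(is.na(stage)) || any(stage != round(stage)) || any(stage < 0)) {
    stop("stage codes must be nonnegative integers (0 = normal control)")
  }
  stage <- as.integer(stage)
  if (length(unique(stage)) < 2) {
    stop("at least 2 distinct stages are required")
  }
  tab <- table(stage)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warning("stage(s) with fewer than 3 samples: ",
            paste(small, collapse = ", "))
  }
  out <- data.frame(sample = samples, stage = stage,
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(samples))
    out$label <- as.character(labels)
  }
  class(out) <- c("stage_design", "data.frame")
  out
}

#' @export
print.stage_design <- function(x, ...) {
  tab <- table(x$stage)
  cat(sprintf("stage_design: %d samples, %d stages%s\n", nrow(x),
              length(tab), if (0L %in% x$stage) " (incl. control, stage 0)"
              else ""))
  print(tab)
  invisible(x)
}

#' Kruskal-Wallis test of one gene across stages
#'
#' Tie-corrected Kruskal-Wallis H statistic over the stage groups with its
#' chi-square upper-tail p-value on K-1 degrees of freedom (via
#' [stats::kruskal.test()]). A gene with zero variance carries no rank
#' information and is assigned `(H = 0, p = 1)` rather than dropped, so the
#' multiple-testing family size stays equal to the gene count.
#'
#' @param values Numeric vector, one value per sample.
#' @param design A [stage_design()] covering the same samples in order.
#'
#' @return List with elements `statistic` and `p`.
#' @export
kruskal_wallis <- function(values, design) {
  stopifnot(inherits(design, "stage_design"))
  values <- as.numeric(values)
  if (length(values) != nrow(design)) {
    stop("length(values) must equal the number of samples in the design")
  }
  if (any(!is.finite(values))) stop("non-finite expression value")
  g <- factor(design$stage)
  if (nlevels(g) < 2) stop("fewer than 2 stages")
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p = 1))
  }
  kw <- stats::kruskal.test(values, g)
  list(statistic = unname(kw$statistic), p = unname(kw$p.value))
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up by default (the standard choice for
#' genome-wide expression screens); Bonferroni and no adjustment are
#' available. Thin wrapper over [stats::p.adjust()] with input validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"`, `"bonferroni"` or `"none"`.
#'
#' @return Adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = method)
}

#' Classify a stage-mean profile as monotone
#'
#' A profile is monotonically increasing (`"MI"`) when the stage means are
#' nondecreasing with at least one strict increase, monotonically decreasing
#' (`"MD"`) when nonincreasing with at least one strict decrease, and
#' `"none"` otherwise. Ties between adjacent stages are allowed inside a
#' monotone chain; an all-constant profile is `"none"` (a flat gene is not
#' differentially expressed in any direction).
#'
#' @param stage_means Numeric vector of per-stage mean expression, ordered
#'   by stage (control first when present); length >= 2, finite.
#'
#' @return `"MI"`, `"MD"` or `"none"`.
#' @examples
#' monotonic_direction(c(1, 1, 2, 2))  # "MI"
#' monotonic_direction(c(2, 2, 2, 2))  # "none"
#' @export
monotonic_direction <- function(stage_means) {
  stage_means <- as.numeric(stage_means)
  if (length(stage_means) < 2) stop("need at least 2 stage means")
  if (any(!is.finite(stage_means))) stop("non-finite stage mean")
  d <- diff(stage_means)
  if (all(d >= 0) && any(d > 0)) return("MI")
  if (all(d <= 0) && any(d < 0)) return("MD")
  "none"
}

#' Identify monotonically expressed genes
#'
#' The three-step screen: per-gene Kruskal-Wallis test across stage groups,
#' multiple-testing adjustment across all genes, and monotone classification
#' of the stage-mean profile. A gene is called `"MI"`/`"MD"` only when its
#' adjusted p-value passes `alpha`; its unthresholded profile shape is kept
#' in the `trend` column so MI/MD counts can be re-derived at any other
#' threshold without re-testing (see [meg_summary()]).
#'
#' Run on a raw expression matrix this is the conventional Kruskal-Wallis
#' baseline; run on [generank_matrix()] output it is the network-weighted
#' procedure. At `d = 0` the two coincide exactly.
#'
#' @param x Numeric genes x samples matrix (raw or GeneRank-weighted), with
#'   dimnames.
#' @param design A [stage_design()]; its samples must be exactly the columns
#'   of `x` (any order).
#' @param alpha Significance threshold on adjusted p-values, in (0, 1).
#' @param adjust Adjustment method, see [adjust_pvalues()].
#' @param control_in_test Include control samples (stage 0) as their own
#'   group in the Kruskal-Wallis test (default). With `FALSE`, controls
#'   enter only the stage-mean chain, not the test.
#'
#' @return A `meg_table` data.frame with one row per gene: `gene`,
#'   `kw_statistic`, `p_raw`, `p_adjusted`, one `mean_stage<k>` column per
#'   stage present (in stage order), `trend` and `direction`; attributes
#'   `alpha`, `mi_count`, `md_count`. Row order is input gene order.
#' @export
identify_megs <- function(x, design, alpha = 0.1,
                          adjust = c("BH", "bonferroni", "none"),
                          control_in_test = TRUE) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(design, "stage_design"))
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("x must have gene rownames and sample colnames")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  if (!setequal(colnames(x), design$sample) ||
      ncol(x) != nrow(design)) {
    stop("sample axes of x and design do not match")
  }
  design <- design[match(colnames(x), design$sample), , drop = FALSE]
  stage <- design$stage
  stages <- sort(unique(stage))
  g_all <- factor(stage, levels = stages)

  test_cols <- if (control_in_test) seq_along(stage) else which(stage != 0L)
  d_test <- stage_design(design$sample[test_cols], stage[test_cols])

  p <- nrow(x)
  kw_stat <- kw_p <- numeric(p)
  for (i in seq_len(p)) {
    kw <- kruskal_wallis(x[i, test_cols], d_test)
    kw_stat[i] <- kw$statistic
    kw_p[i] <- kw$p
  }
  p_adj <- adjust_pvalues(kw_p, adjust)

  counts <- as.integer(table(g_all))
  means <- t(rowsum(t(x), g_all) / counts)  # p x K, stage order
  colnames(means) <- paste0("mean_stage", stages)

  trend <- apply(means, 1, monotonic_direction)
  direction <- ifelse(p_adj <= alpha, trend, "none")

  out <- data.frame(gene = rownames(x), kw_statistic = kw_stat,
                    p_raw = kw_p, p_adjusted = p_adj,
                    means, trend = trend, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "stages") <- stages
  attr(out, "mi_count") <- sum(direction == "MI")
  attr(out, "md_count") <- sum(direction == "MD")
  class(out) <- c("meg_table", "data.frame")
  out
}

#' MI/MD counts over a grid of significance thresholds
#'
#' Recomputes, from a fitted `meg_table`, how many genes would be called
#' monotonically increasing or decreasing at each threshold of an
#' adjusted-p grid. Counts are nondecreasing in the threshold by
#' construction.
#'
#' @param tab A `meg_table` from [identify_megs()].
#' @param alpha_grid Numeric thresholds; default the conventional grid
#'   `c(0.05, 0.1, 0.15, 0.2)`.
#'
#' @return data.frame with columns `alpha`, `MI`, `MD`.
#' @export
meg_summary <- function(tab, alpha_grid = c(0.05, 0.1, 0.15, 0.2)) {
  stopifnot(inherits(tab, "meg_table"))
  data.frame(
    alpha = alpha_grid,
    MI = vapply(alpha_grid, function(a)
      sum(tab$p_adjusted <= a & tab$trend == "MI"), 0L),
    MD = vapply(alpha_grid, function(a)
      sum(tab$p_adjusted <= a & tab$trend == "MD"), 0L)
  )
}

#' @export
print.meg_table <- function(x, ...) {
  cat(sprintf(
    "meg_table: %d genes, alpha = %g -> %d MI, %d MD\n", nrow(x),
    attr(x, "alpha"), attr(x, "mi_count"), attr(x, "md_count")))
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
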