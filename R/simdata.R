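#' Simulate a gene-interaction network
#'
#' Random undirected networks standing in for a curated protein-interaction
#' resource: an Erdos-Renyi G(p, prob) model, or a Barabasi-Albert
#' preferential-attachment model whose heavy-tailed degrees mimic the
#' hub-dominated structure of real interactomes. Generation is delegated to
#' [igraph::sample_gnp()] / [igraph::sample_pa()] and the result wrapped as
#' a [gene_network()] over genes `g1..gp`.
#'
#' @param p Number of genes, >= 2.
#' @param model `"erdos_renyi"` or `"scale_free"`.
#' @param param Edge probability in `[0, 1]` (erdos_renyi) or integer
#'   attachment count m >= 1 (scale_free). For scale_free the edge count is
#'   deterministic: vertex k contributes `min(m, k - 1)` edges.
#' @param seed Integer seed (local to this call).
#'
#' @return A [gene_network()].
#' @examples
#' simulate_network(50, "erdos_renyi", 0.1, seed = 1)
#' @export
simulate_network <- function(p, model = c("erdos_renyi", "scale_free"),
                             param, seed = NULL) {
  model <- match.arg(model)
  if (!is.numeric(p) || length(p) != 1 || p < 2 || p != round(p)) {
    stop("p must be an integer >= 2")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  g <- switch(model,
    erdos_renyi = {
      if (!is.numeric(param) || param < 0 || param > 1) {
        stop("erdos_renyi needs an edge probability in [0, 1]")
      }
      igraph::sample_gnp(p, param)
    },
    scale_free = {
      if (!is.numeric(param) || param < 1 || param != round(param)) {
        stop("scale_free needs an integer attachment count >= 1")
      }
      igraph::sample_pa(p, power = 1, m = param, directed = FALSE,
                        algorithm = "psumtree")
    })
  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  gene_network(paste0("g", seq_len(p)), adj)
}

#' Simulate an expression matrix with planted monotone genes
#'
#' Generates a genes x samples matrix on a log-like scale (Gaussian noise
#' around a constant baseline, emulating microarray summaries or
#' log2(FPKM+1) values) with a minority of genes planted as monotonically
#' increasing (MI) or decreasing (MD): a planted MI gene's mean at the k-th
#' stage group (0-based from the first group) is
#' `baseline + k * effect_step * noise_sd`, an MD gene's is its mirror
#' image. Background genes are i.i.d. noise. `shape = "plateau"` applies
#' the per-stage step only over the first half of the stage transitions and
#' is then flat, which exercises the tie-tolerant monotone chain.
#'
#' Planted genes occupy the first `n_mi + n_md` rows by default; with
#' `hub_planted = TRUE` and a network supplied, gene names are assigned so
#' the planted genes sit on the highest-degree (hub) nodes, exercising the
#' network weighting where it is designed to help.
#'
#' @param p Total number of genes, >= `n_mi + n_md`.
#' @param stage_sizes Integer samples per stage group, in stage order;
#'   default four stages of 15.
#' @param n_mi,n_md Planted monotonically increasing / decreasing genes.
#' @param effect_step Mean shift per stage increment, in units of
#'   `noise_sd`; default 1.
#' @param noise_sd Within-group standard deviation; default 1.
#' @param baseline Background mean on the log-like scale; default 7.
#' @param include_control Treat the first stage group as a normal-control
#'   group (stage code 0) instead of stage 1.
#' @param shape `"linear"` or `"plateau"`.
#' @param network Optional [gene_network()] supplying the gene universe
#'   (its gene count must equal `p`).
#' @param hub_planted Place planted genes on the highest-degree network
#'   nodes; requires `network`.
#' @param seed Integer seed (local to this call).
#'
#' @return List with `expr` (matrix), `design` ([stage_design()]) and
#'   `truth` (list: `mi_genes`, `md_genes`, `effect_step`, `noise_sd`,
#'   `stage_sizes`, `seed`).
#' @export
simulate_expression <- function(p, stage_sizes = c(15, 15, 15, 15),
                                n_mi = 50, n_md = 50, effect_step = 1,
                                noise_sd = 1, baseline = 7,
                                include_control = FALSE,
                                shape = c("linear", "plateau"),
                                network = NULL, hub_planted = FALSE,
                                seed = NULL) {
  shape <- match.arg(shape)
  if (length(stage_sizes) < 2 || any(stage_sizes < 1)) {
    stop("need at least 2 stage groups with >= 1 sample each")
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (effect_step < 0) stop("effect_step must be >= 0")
  if (p < n_mi + n_md) stop("p must be >= n_mi + n_md")
  if (hub_planted && is.null(network)) {
    stop("hub_planted = TRUE requires a network")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  K <- length(stage_sizes)
  n <- sum(stage_sizes)
  stage0 <- if (include_control) 0L else 1L
  stage <- rep(seq(stage0, length.out = K), stage_sizes)
  samples <- sprintf("s%03d", seq_len(n))

  genes <- if (!is.null(network)) {
    if (length(network$genes) != p) {
      stop("network gene count must equal p")
    }
    network$genes
  } else {
    sprintf("g%04d", seq_len(p))
  }
  planted_slots <- if (hub_planted) {
    order(network$degree, decreasing = TRUE)[seq_len(n_mi + n_md)]
  } else {
    seq_len(n_mi + n_md)
  }
  mi_genes <- genes[planted_slots[seq_len(n_mi)]]
  md_genes <- genes[planted_slots[n_mi + seq_len(n_md)]]

  # per-stage-position offsets (0-based position within the group sequence)
  pos <- rep(seq_len(K) - 1L, stage_sizes)
  incr <- if (shape == "linear") {
    pos
  } else {
    pmin(pos, ceiling((K - 1) / 2))  # rises over the first half, then flat
  }
  offset <- incr * effect_step * noise_sd

  expr <- matrix(stats::rnorm(p * n, mean = baseline, sd = noise_sd),
                 nrow = p, ncol = n, dimnames = list(genes, samples))
  if (n_mi > 0) {
    expr[mi_genes, ] <- expr[mi_genes, ] + rep(offset, each = n_mi)
  }
  if (n_md > 0) {
    expr[md_genes, ] <- expr[md_genes, ] - rep(offset, each = n_md)
  }
  attr(expr, "scale_note") <- "simulated log-like expression"

  list(expr = expr,
       design = stage_design(samples, stage),
       truth = list(mi_genes = mi_genes, md_genes = md_genes,
                    effect_step = effect_step, noise_sd = noise_sd,
                    stage_sizes = stage_sizes, seed = seed))
}
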