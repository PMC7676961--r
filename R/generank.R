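#' @keywords internal
#' @noRd
.generank_system <- function(net, d) {
  if (!inherits(net, "gene_network")) stop("'net' must be a gene_network")
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d < 0 || d >= 1) {
    stop("damping parameter d must lie in [0, 1); at d = 1 the system ",
         "(I - W D^-1) is singular")
  }
  p <- length(net$genes)
  # zero-degree convention: isolated genes get a unit diagonal in D so the
  # column scaling is defined; their W column is all-zero, so the solution
  # for them is r = (1 - d) e either way.
  dtil <- pmax(net$degree, 1)
  Matrix::Diagonal(p) - d * (net$adjacency %*% Matrix::Diagonal(x = 1 / dtil))
}

#' GeneRank of a single sample
#'
#' Solves the GeneRank linear system
#' \deqn{(I_p - d W \tilde{D}^{-1})\, r = (1 - d)\, e}
#' for one sample's expression vector \eqn{e}, where \eqn{W} is the binary
#' gene-interaction adjacency and \eqn{\tilde{D}} the diagonal degree matrix
#' (isolated genes get a unit diagonal entry, which leaves their solution
#' \eqn{r_k = (1-d)e_k} untouched). The damping parameter `d` trades off
#' expression against network topology: at `d = 0` the ranking is the
#' expression vector itself; as `d` grows the network dominates. `d = 1`
#' makes the system singular and is rejected.
#'
#' The solve is direct (dense below 500 genes, sparse LU above) and the
#' result is guaranteed to satisfy the residual contract
#' \eqn{\|(I - dW\tilde{D}^{-1})r - (1-d)e\|_\infty \le}
#' `solver_tol * max(1, max|e|)`; one step of iterative refinement is applied
#' if the first solve falls short.
#'
#' @param net A [gene_network()] whose gene axis matches `expression`.
#' @param expression Numeric vector of expression values, one per network
#'   gene, finite. Values are used as-is (no rank transform, no shift); see
#'   [generank_matrix()] for optional transforms.
#' @param d Damping parameter in `[0, 1)`; default `0.5`.
#' @param solver_tol Residual tolerance of the solve; default `1e-8`.
#'
#' @return Numeric vector `r` of length `p`, named by gene.
#' @examples
#' net <- gene_network(c("A", "B", "C"),
#'                     rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
#' generank_sample(net, c(1, 0, 0), d = 0.5)  # (7/12, 1/3, 1/12)
#' @export
generank_sample <- function(net, expression, d = 0.5, solver_tol = 1e-8) {
  A <- .generank_system(net, d)
  p <- length(net$genes)
  expression <- as.numeric(expression)
  if (length(expression) != p) {
    stop("expression length (", length(expression),
         ") does not match network gene count (", p, ")")
  }
  bad <- which(!is.finite(expression))
  if (length(bad)) {
    stop("non-finite expression value for gene ",
         paste(net$genes[bad], collapse = ", "))
  }
  r <- .generank_solve(A, matrix((1 - d) * expression, ncol = 1),
                       solver_tol, p)
  stats::setNames(as.numeric(r), net$genes)
}

#' @keywords internal
#' @noRd
.generank_solve <- function(A, B, solver_tol, p) {
  solve_once <- if (p < 500) {
    Ad <- as.matrix(A)
    function(rhs) solve(Ad, rhs)
  } else {
    function(rhs) as.matrix(Matrix::solve(A, rhs, sparse = FALSE))
  }
  R <- solve_once(B)
  resid <- as.matrix(A %*% R - B)
  bound <- solver_tol * pmax(1, apply(abs(B), 2, max))
  off <- apply(abs(resid), 2, max) > bound
  if (any(off)) {  # one round of iterative refinement
    R[, off] <- R[, off, drop = FALSE] - solve_once(resid[, off, drop = FALSE])
    resid <- as.matrix(A %*% R - B)
    if (any(apply(abs(resid), 2, max) > bound)) {
      stop("GeneRank solve failed the residual contract (tol = ",
           solver_tol, "); the system may be badly conditioned")
    }
  }
  R
}

#' GeneRank-weighted expression matrix
#'
#' Applies [generank_sample()] column-wise to a genes x samples expression
#' matrix, factoring the system matrix once, and returns the weighted
#' expression matrix the downstream monotone-gene screen consumes. The gene
#' axis of `expr` must match the network exactly (use [align_to_genes()]
#' first).
#'
#' The solved vector `r` is used directly as the weighted expression by
#' default. `rank_transform = TRUE` replaces each column by its within-sample
#' ranks after solving, for workflows that want a scale-free weighting;
#' `shift_nonneg = TRUE` shifts each column of `expr` by its (negative)
#' minimum before solving, for inputs centred below zero, since the original
#' GeneRank formulation assumes nonnegative expression.
#'
#' @param net A [gene_network()] aligned to `rownames(expr)`.
#' @param expr Numeric genes x samples matrix with dimnames.
#' @param d,solver_tol As in [generank_sample()].
#' @param rank_transform,shift_nonneg Optional transforms, default off.
#'
#' @return A numeric matrix of the same shape and dimnames as `expr`, with
#'   attributes `damping` (d) and `scale_note`.
#' @export
generank_matrix <- function(net, expr, d = 0.5, solver_tol = 1e-8,
                            rank_transform = FALSE, shift_nonneg = FALSE) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expr must have gene rownames")
  if (!identical(rownames(expr), net$genes)) {
    stop("gene axis of expr does not match the network; ",
         "call align_to_genes(net, rownames(expr)) first")
  }
  if (ncol(expr) < 1) stop("expr needs at least one sample column")
  if (any(!is.finite(expr))) stop("expr contains non-finite values")
  if (shift_nonneg) {
    mins <- pmin(apply(expr, 2, min), 0)
    expr <- sweep(expr, 2, mins, "-")
  }
  A <- .generank_system(net, d)
  R <- .generank_solve(A, (1 - d) * expr, solver_tol, nrow(expr))
  if (rank_transform) R <- apply(R, 2, rank)
  dimnames(R) <- dimnames(expr)
  attr(R, "damping") <- d
  attr(R, "scale_note") <- if (rank_transform) {
    sprintf("within-sample ranks of GeneRank (d = %g)", d)
  } else {
    sprintf("GeneRank-weighted expression (d = %g)", d)
  }
  R
}
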