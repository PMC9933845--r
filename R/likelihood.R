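# Site-pattern compression over a set of alignment rows: identical columns
# are collapsed and weighted, which is exact because per-site likelihoods
# depend only on the column content.
compress_columns <- function(aln, row_labels) {
  missing <- setdiff(row_labels, names(aln$seqs))
  if (length(missing) > 0L) {
    stop("leaf without sequence: ", paste(missing, collapse = ", "))
  }
  m <- alignment_matrix(subset_alignment(aln, row_labels))
  key <- do.call(paste0, as.data.frame(t(m), stringsAsFactors = FALSE))
  first <- !duplicated(key)
  rep_cols <- which(first)
  pattern_id <- match(key, key[first])
  weights <- tabulate(pattern_id, nbins = length(rep_cols))
  list(matrix = m[, rep_cols, drop = FALSE], rep_cols = rep_cols,
       pattern_id = pattern_id, weights = as.numeric(weights),
       n_columns = aln$L)
}

# 4 x P x ntip cube of leaf partials, tips ordered by tree tip ids.
tip_partial_cube <- function(tree, comp) {
  ntip <- length(tree$tip.label)
  P <- ncol(comp$matrix)
  cube <- array(0, dim = c(4L, P, ntip))
  for (i in seq_len(ntip)) {
    chars <- comp$matrix[tree$tip.label[i], ]
    for (code in unique(chars)) {
      cube[match(IUPAC_MAP[[code]], DNA_STATES), chars == code, i] <- 1
    }
  }
  cube
}

#' Two-directional conditional likelihoods for every edge
#'
#' Runs one post-order and one pre-order Felsenstein-pruning pass and caches,
#' for every node, the conditional likelihood of the subtree below it
#' (`down`) and of the rest of the tree seen from its parent (`up`), per
#' site pattern and Gamma category, with per-site log scaling to prevent
#' underflow. Combining the two directions across any edge reproduces the
#' total log-likelihood (the pulley principle for reversible models), which
#' is what makes O(sites) per-edge attachment scoring possible.
#'
#' @param tree Edge-numbered `"phylo"` backbone tree with branch lengths.
#' @param model A [gtr_gamma_model()].
#' @param alignment An [aligned_seqs()] alignment containing every leaf.
#' @param extra_rows Optional labels of additional alignment rows (e.g.
#'   query sequences) to include in the site-pattern compression key, so
#'   that cached patterns remain exact when those rows are scored later.
#' @param want_up Compute the pre-order (`up`) direction too (default TRUE).
#' @param comp Optional precomputed site-pattern compression (internal
#'   reuse across repeated evaluations on the same alignment rows).
#' @return A `partials_cache` object; its `loglik` element is the total
#'   log-likelihood of the backbone tree and `site_loglik` the per-column
#'   log-likelihoods.
#' @export
compute_edge_partials <- function(tree, model, alignment, extra_rows = character(),
                                  want_up = TRUE, comp = NULL) {
  stopifnot(inherits(model, "gtr_gamma"))
  tree <- require_edge_numbers(tree)
  if (is.null(comp)) {
    rows <- unique(c(tree$tip.label, extra_rows))
    comp <- compress_columns(alignment, rows)
  }
  if (is.null(comp$tipL)) comp$tipL <- tip_partial_cube(tree, comp)
  res <- cpp_partials(postorder_nodes(tree), parent_vec(tree),
                      length_above(tree), comp$tipL,
                      length(tree$tip.label),
                      model$eigen$A, model$eigen$B, model$eigen$lambda,
                      model$pi, model$rates, want_up)
  structure(list(tree = tree, model = model, comp = comp,
                 down = res$down, down_ls = res$down_ls,
                 up = res$up, up_ls = res$up_ls,
                 pattern_loglik = res$site_loglik,
                 site_loglik = res$site_loglik[comp$pattern_id],
                 loglik = sum(res$site_loglik * comp$weights),
                 has_up = want_up),
            class = "partials_cache")
}

#' @export
print.partials_cache <- function(x, ...) {
  cat("Partials cache: ", length(x$tree$tip.label), " leaves, ",
      length(x$comp$weights), " site patterns (", x$comp$n_columns,
      " columns), logL = ", format(x$loglik, digits = 10), "\n", sep = "")
  invisible(x)
}

#' Tree log-likelihood under GTR+Gamma
#'
#' Felsenstein-pruning log-likelihood of an alignment on a fixed tree. Gap
#' and ambiguity characters contribute partial-likelihood vectors of ones
#' (missing data). Per-site values average the Gamma categories with equal
#' weights.
#'
#' @inheritParams compute_edge_partials
#' @return List with `loglik` (total) and `site_loglik` (per alignment
#'   column).
#' @export
compute_loglikelihood <- function(tree, model, alignment) {
  tree <- require_edge_numbers(tree)
  comp <- compress_columns(alignment, tree$tip.label)
  comp$tipL <- tip_partial_cube(tree, comp)
  res <- tree_loglik_comp(tree, model, comp)
  list(loglik = res$loglik, site_loglik = res$site_loglik[comp$pattern_id])
}

# Fast total log-likelihood on a precompressed alignment (no partials kept).
tree_loglik_comp <- function(tree, model, comp) {
  cpp_tree_loglik(postorder_nodes(tree), parent_vec(tree),
                  length_above(tree), comp$tipL, length(tree$tip.label),
                  model$eigen$A, model$eigen$B, model$eigen$lambda,
                  model$pi, model$rates, comp$weights)
}

# Base-tree log-likelihood evaluated across the edge above `child`, with
# that edge's length replaced by `t`. Exact for any edge by reversibility.
edge_loglik_at_length <- function(cache, child, t) {
  cpp_attach_loglik(cache$model$eigen$A, cache$model$eigen$B,
                    cache$model$eigen$lambda, cache$model$pi,
                    cache$model$rates,
                    cache$down[[child]], cache$down_ls[[child]],
                    cache$up[[child]], cache$up_ls[[child]],
                    matrix(1, 1, 1), cache$comp$weights, t, 0, 0, FALSE)
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-ascent branch-length optimization: each branch in turn is
#' optimized by Brent's bounded scalar search on `[1e-8, 20]` expected
#' substitutions/site, using cached directional partials so each evaluation
#' costs O(sites). Sweeps repeat until the total log-likelihood improves by
#' less than `tol`; every accepted update is checked to be non-decreasing,
#' so the returned log-likelihood trace is monotone.
#'
#' @inheritParams compute_edge_partials
#' @param tol Convergence tolerance in log-likelihood units (default 1e-4).
#' @param max_sweeps Maximum number of full sweeps (default 50); a warning
#'   is issued and the best tree so far returned if reached.
#' @return List with `tree` (updated lengths, canonical edge numbers),
#'   `loglik`, and `trace` (log-likelihood after each accepted sweep,
#'   starting with the initial value).
#' @export
optimize_branch_lengths <- function(tree, model, alignment, tol = 1e-4,
                                    max_sweeps = 50L) {
  stopifnot(tol > 0)
  tree <- require_edge_numbers(tree)
  comp <- compress_columns(alignment, tree$tip.label)
  comp$tipL <- tip_partial_cube(tree, comp)
  cache <- compute_edge_partials(tree, model, alignment, comp = comp)
  cur <- cache$loglik
  trace <- cur
  converged <- FALSE
  dummy_q <- matrix(1, 1, 1)
  opt_edge <- function(cache, v, t_now) {
    m <- cache$model
    cpp_optimize_attachment(m$eigen$A, m$eigen$B, m$eigen$lambda, m$pi,
                            m$rates, cache$down[[v]], cache$down_ls[[v]],
                            cache$up[[v]], cache$up_ls[[v]], dummy_q,
                            cache$comp$weights,
                            b = 0, xlo = BRANCH_LOWER, xhi = BRANCH_UPPER,
                            x0 = t_now, p0 = 0,
                            plo = 0, phi = 0,
                            use_query = FALSE, split_edge = FALSE,
                            opt_x = TRUE, opt_p = FALSE,
                            max_rounds = 1L, tol = tol,
                            xtol = 1e-5, ptol = 1, stop_below = -Inf)
  }
  for (sweep in seq_len(max_sweeps)) {
    children <- tree$edge[, 2L]
    # Jacobi proposal: optimize every edge against the current cache
    proposal <- tree$edge.length
    for (i in seq_along(children)) {
      res <- opt_edge(cache, children[i], tree$edge.length[i])
      proposal[i] <- res[1L]
    }
    cand <- tree
    cand$edge.length <- proposal
    cand_cache <- compute_edge_partials(cand, model, alignment, comp = comp)
    if (cand_cache$loglik >= cur - 1e-9) {
      accepted <- max(cand_cache$loglik, cur)
      tree <- cand
      cache <- cand_cache
    } else {
      # Simultaneous updates overshot: fall back to sequential (Gauss-
      # Seidel) updates with a fresh cache per edge, which cannot decrease.
      for (i in seq_along(children)) {
        res <- opt_edge(cache, children[i], tree$edge.length[i])
        if (res[3L] > edge_loglik_at_length(cache, children[i],
                                            tree$edge.length[i]) + 1e-12) {
          tree$edge.length[i] <- res[1L]
          cache <- compute_edge_partials(tree, model, alignment, comp = comp)
        }
      }
      accepted <- cache$loglik
    }
    improvement <- accepted - cur
    cur <- max(accepted, cur)
    trace <- c(trace, cur)
    if (improvement < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("branch-length optimization did not converge in ", max_sweeps,
            " sweeps; returning best tree so far")
  }
  list(tree = tree, loglik = cur, trace = trace)
}

# Branch-length search bracket, in expected substitutions per site; zero is
# excluded to keep P(t) nondegenerate.
BRANCH_LOWER <- 1e-8
BRANCH_UPPER <- 20

#' Estimate GTR+Gamma parameters on a fixed topology
#'
#' Numeric-parameter estimation stage: base frequencies are set empirically
#' from alignment counts (gaps and ambiguities excluded, pseudocount 0.5 per
#' state), while exchangeabilities (GT-normalized to 1) and the Gamma shape
#' are optimized by bounded ascent on the log scale, interleaved with
#' branch-length sweeps. This is a functional stand-in for running an
#' external program such as FastTree or RAxML over the backbone: it fixes
#' the topology and fits only numeric parameters.
#'
#' @inheritParams optimize_branch_lengths
#' @param optimize Character subset of
#'   `c("branch_lengths", "exchangeabilities", "alpha")` selecting which
#'   parameter blocks to fit.
#' @param n_categories Number of discrete Gamma categories (default 4).
#' @param rounds Outer rounds interleaving rate-parameter and branch-length
#'   fits (default 2).
#' @param nm_maxit Nelder-Mead iteration cap per rate-parameter fit.
#' @return List with `model`, `tree`, `loglik`, and `loglik_initial`.
#' @export
estimate_model_parameters <- function(tree, alignment,
                                      optimize = c("branch_lengths",
                                                   "exchangeabilities",
                                                   "alpha"),
                                      n_categories = 4L, tol = 1e-4,
                                      rounds = 2L, nm_maxit = 80L) {
  tree <- require_edge_numbers(tree)
  optimize <- match.arg(optimize, several.ok = TRUE)
  pi <- empirical_base_freqs(alignment, tree$tip.label)
  comp <- compress_columns(alignment, tree$tip.label)
  variable <- apply(comp$matrix, 2, function(col) {
    obs <- unique(col[col %in% DNA_STATES])
    length(obs) > 1L
  })
  if (!any(variable)) {
    warning("alignment has no variable sites; returning JC-like defaults")
    model <- gtr_gamma_model(rep(1, 6), pi, alpha = 100,
                             n_categories = n_categories)
    ll <- compute_loglikelihood(tree, model, alignment)$loglik
    return(list(model = model, tree = tree, loglik = ll,
                loglik_initial = ll))
  }

  comp$tipL <- tip_partial_cube(tree, comp)
  exch <- rep(1, 6)
  alpha <- 1
  model <- gtr_gamma_model(exch, pi, alpha, n_categories)
  ll0 <- tree_loglik_comp(tree, model, comp)$loglik
  ll <- ll0

  fit_rates <- any(c("exchangeabilities", "alpha") %in% optimize)
  for (round in seq_len(rounds)) {
    if ("branch_lengths" %in% optimize) {
      bl <- optimize_branch_lengths(tree, model, alignment, tol = tol)
      tree <- bl$tree
      ll <- bl$loglik
    }
    if (fit_rates) {
      fit_exch <- "exchangeabilities" %in% optimize
      fit_alpha <- "alpha" %in% optimize
      par <- c(if (fit_exch) log(exch[1:5]), if (fit_alpha) log(alpha))
      objective <- function(p) {
        i <- 0L
        e <- exch
        if (fit_exch) { e <- c(exp(pmin(pmax(p[1:5], -10), 10)), 1); i <- 5L }
        a <- alpha
        if (fit_alpha) a <- exp(pmin(pmax(p[i + 1L], log(0.01)), log(100)))
        m <- gtr_gamma_model(e, pi, a, n_categories)
        -tree_loglik_comp(tree, m, comp)$loglik
      }
      fit <- stats::optim(par, objective, method = "Nelder-Mead",
                          control = list(maxit = nm_maxit))
      p <- fit$par
      i <- 0L
      if (fit_exch) {
        exch <- c(exp(pmin(pmax(p[1:5], -10), 10)), 1)
        i <- 5L
      }
      if (fit_alpha) alpha <- exp(pmin(pmax(p[i + 1L], log(0.01)), log(100)))
      model <- gtr_gamma_model(exch, pi, alpha, n_categories)
      ll <- max(ll, -fit$value)
    }
  }
  ll <- tree_loglik_comp(tree, model, comp)$loglik
  list(model = model, tree = tree, loglik = ll, loglik_initial = ll0)
}

#' Empirical base frequencies of an alignment
#'
#' Counts A, C, G, T over the given rows (gaps and ambiguity codes are
#' excluded) with a pseudocount of 0.5 per state, which keeps all four
#' frequencies strictly positive as required by the reversible
#' eigendecomposition.
#'
#' @param alignment An `aligned_seqs` object.
#' @param rows Row labels to count over (default: all rows).
#' @return Numeric vector of 4 frequencies (A, C, G, T) summing to 1.
#' @export
empirical_base_freqs <- function(alignment, rows = NULL) {
  if (is.null(rows)) rows <- names(alignment$seqs)
  chars <- strsplit(paste(alignment$seqs[rows], collapse = ""), "")[[1]]
  counts <- vapply(DNA_STATES, function(s) sum(chars == s), numeric(1)) + 0.5
  unname(counts / sum(counts))
}
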