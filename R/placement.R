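# Query leaf-partial matrix on the cache's pattern columns, validating that
# the row is constant within every site pattern (guaranteed when the row was
# included in the cache's compression key via `extra_rows`).
query_pattern_partials <- function(cache, query_row) {
  chars <- strsplit(toupper(query_row), "")[[1]]
  if (length(chars) != cache$comp$n_columns) {
    stop("query length ", length(chars), " does not match alignment width ",
         cache$comp$n_columns)
  }
  if (any(chars != chars[cache$comp$rep_cols][cache$comp$pattern_id])) {
    stop("query sequence is inconsistent with the cache's site patterns; ",
         "rebuild the cache with this query in `extra_rows`")
  }
  leaf_partials(paste(chars[cache$comp$rep_cols], collapse = ""))
}

#' Log-likelihood of a query attachment
#'
#' Scores the tree obtained by splitting the given edge at `distal_length`
#' from its child (leafward) end and attaching the query by a pendant
#' branch of `pendant_length`, in O(sites x categories) per call from the
#' cached directional partials. The value equals the full pruning
#' log-likelihood of the explicitly extended tree.
#'
#' @param cache A [compute_edge_partials()] cache built with the query row
#'   in `extra_rows` (or with an uncompressible alignment).
#' @param query_row Aligned query sequence (string over the backbone's
#'   column space) or the label of a row included in the cache.
#' @param edge_number Backbone edge to attach to.
#' @param distal_length Attachment offset from the child end, in
#'   `[0, edge length]`.
#' @param pendant_length Query pendant branch length (`>= 0`).
#' @return The log-likelihood of the extended tree.
#' @export
attachment_loglikelihood <- function(cache, query_row, edge_number,
                                     distal_length, pendant_length) {
  stopifnot(inherits(cache, "partials_cache"))
  if (!cache$has_up) stop("cache was built with want_up = FALSE")
  tree <- cache$tree
  v <- child_of_edge_number(tree, edge_number)
  b <- length_above(tree)[v]
  if (distal_length < -1e-12 || distal_length > b + 1e-9) {
    stop("distal_length ", distal_length, " outside edge of length ", b)
  }
  if (pendant_length < 0) stop("pendant_length must be >= 0")
  distal_length <- min(max(distal_length, 0), b)
  Qtip <- resolve_query_partials(cache, query_row)
  attach_ll(cache, v, Qtip, distal_length, b - distal_length, pendant_length)
}

resolve_query_partials <- function(cache, query_row) {
  # `query_row` may be the label of a row already in the cache's pattern
  # matrix, or a full aligned sequence string.
  if (query_row %in% rownames(cache$comp$matrix) &&
      nchar(query_row) != cache$comp$n_columns) {
    return(leaf_partials(paste(cache$comp$matrix[query_row, ], collapse = "")))
  }
  query_pattern_partials(cache, query_row)
}

attach_ll <- function(cache, child, Qtip, tx, tu, tp) {
  m <- cache$model
  cpp_attach_loglik(m$eigen$A, m$eigen$B, m$eigen$lambda, m$pi, m$rates,
                    cache$down[[child]], cache$down_ls[[child]],
                    cache$up[[child]], cache$up_ls[[child]],
                    Qtip, cache$comp$weights, tx, tu, tp, TRUE)
}

PENDANT_LOWER <- 1e-8
PENDANT_UPPER <- 5

#' Maximum-likelihood placement of one query
#'
#' Scores the attachment of an aligned query sequence on every edge of the
#' backbone tree and returns the edge maximizing the likelihood of the
#' extended tree. On each edge the attachment geometry (distal offset `x`,
#' pendant length `p`) is optimized by coordinate ascent with bounded
#' Brent searches, initialized at `x = ` half the edge length and
#' `p = 0.1`; the pendant search bracket is `[1e-8, 5]` substitutions/site.
#' The reported `like_weight_ratio` is the softmax weight of the best edge
#' among all per-edge optimized log-likelihoods (scores more than 50 log
#' units below the best are excluded to avoid underflow). Near-ties
#' (`|delta logL| < 1e-9`) are broken toward the smaller edge number.
#'
#' @param tree Edge-numbered backbone `"phylo"` tree.
#' @param model A [gtr_gamma_model()].
#' @param alignment Alignment holding the backbone rows and the query row,
#'   all in one column space.
#' @param query_name Label of the query row; must not be a backbone leaf.
#' @param optimize_iters Maximum coordinate-ascent rounds per edge
#'   (default 5); rounds stop early once a round improves the edge score by
#'   less than `tol`.
#' @param tol Per-edge convergence tolerance in log-likelihood units.
#' @param cache Optional precomputed [compute_edge_partials()] cache (must
#'   include the query in its compression key).
#' @return A [placement()] with per-edge optimized scores attached.
#' @export
place_query <- function(tree, model, alignment, query_name,
                        optimize_iters = 5L, tol = 1e-4, cache = NULL) {
  tree <- require_edge_numbers(tree)
  if (query_name %in% tree$tip.label) {
    stop("query '", query_name, "' is already a backbone leaf")
  }
  qrow <- get_row(alignment, query_name)
  if (gsub("-", "", qrow, fixed = TRUE) == "") {
    stop("uninformative query '", query_name, "': sequence is all gaps")
  }
  if (is.null(cache)) {
    cache <- compute_edge_partials(tree, model, alignment,
                                   extra_rows = query_name, want_up = TRUE)
  }
  Qtip <- query_pattern_partials(cache, qrow)
  bl <- length_above(cache$tree)
  children <- cache$tree$edge[, 2L]
  enums <- cache$tree$edge_number

  scores <- numeric(length(children))
  geoms <- matrix(0, nrow = length(children), ncol = 2L,
                  dimnames = list(NULL, c("x", "p")))
  m <- cache$model
  best_so_far <- -Inf
  for (i in seq_along(children)) {
    v <- children[i]
    b <- bl[v]
    res <- cpp_optimize_attachment(
      m$eigen$A, m$eigen$B, m$eigen$lambda, m$pi, m$rates,
      cache$down[[v]], cache$down_ls[[v]],
      cache$up[[v]], cache$up_ls[[v]], Qtip, cache$comp$weights,
      b = b, xlo = 0, xhi = b, x0 = b / 2, p0 = 0.1,
      plo = PENDANT_LOWER, phi = PENDANT_UPPER,
      use_query = TRUE, split_edge = TRUE, opt_x = TRUE, opt_p = TRUE,
      max_rounds = optimize_iters, tol = tol,
      xtol = max(b * 0.01, 1e-9), ptol = 0.01,
      stop_below = best_so_far - 60)
    scores[i] <- res[3L]
    geoms[i, ] <- res[1:2]
    if (res[3L] > best_so_far) best_so_far <- res[3L]
  }

  # re-polish every near-contending edge at full resolution before picking
  # the winner, so close calls are decided at fine accuracy
  for (i in which(scores > max(scores) - 1)) {
    vb <- children[i]
    bb <- bl[vb]
    res <- cpp_optimize_attachment(
      m$eigen$A, m$eigen$B, m$eigen$lambda, m$pi, m$rates,
      cache$down[[vb]], cache$down_ls[[vb]],
      cache$up[[vb]], cache$up_ls[[vb]], Qtip, cache$comp$weights,
      b = bb, xlo = 0, xhi = bb, x0 = geoms[i, "x"], p0 = geoms[i, "p"],
      plo = PENDANT_LOWER, phi = PENDANT_UPPER,
      use_query = TRUE, split_edge = TRUE, opt_x = TRUE, opt_p = TRUE,
      max_rounds = 20L, tol = tol * 1e-3,
      xtol = max(bb * 1e-5, 1e-10), ptol = 1e-7, stop_below = -Inf)
    if (res[3L] > scores[i]) {
      scores[i] <- res[3L]
      geoms[i, ] <- res[1:2]
    }
    # joint 2-D refinement closes the narrow diagonal ridges that
    # alternating 1-D searches converge into slowly
    obj <- function(par) {
      -attach_ll(cache, vb, Qtip,
                 min(max(par[1], 0), bb),
                 bb - min(max(par[1], 0), bb),
                 min(max(par[2], PENDANT_LOWER), PENDANT_UPPER))
    }
    nm <- stats::optim(geoms[i, ], obj, method = "Nelder-Mead",
                       control = list(maxit = 200, reltol = 1e-14))
    if (-nm$value > scores[i]) {
      scores[i] <- -nm$value
      geoms[i, ] <- c(min(max(nm$par[1], 0), bb),
                      min(max(nm$par[2], PENDANT_LOWER), PENDANT_UPPER))
    }
  }
  best_score <- max(scores)
  cand <- which(scores > best_score - 1e-9)
  best <- cand[which.min(enums[cand])]
  keep <- scores > best_score - 50
  w <- exp(scores[keep] - best_score)
  lwr <- exp(scores[best] - best_score) / sum(w)
  placement(query_name = query_name,
            edge_number = enums[best],
            distal_length = geoms[best, "x"],
            pendant_length = geoms[best, "p"],
            log_likelihood = scores[best],
            like_weight_ratio = min(lwr, 1),
            per_edge_scores = stats::setNames(scores, enums))
}

#' Likelihood-weight ratios over all edges
#'
#' Softmax of the per-edge optimized scores stored in a placement; sums to
#' 1 over the retained edges.
#'
#' @param pl A [placement()] with `per_edge_scores`.
#' @return Named numeric vector of weights (names = edge numbers).
#' @export
like_weight_ratios <- function(pl) {
  stopifnot(inherits(pl, "placement"), !is.null(pl$per_edge_scores))
  s <- pl$per_edge_scores
  m <- max(s)
  w <- exp(s - m)
  w[s <= m - 50] <- 0
  w / sum(w)
}
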