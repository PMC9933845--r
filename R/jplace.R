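#' Create a placement record
#'
#' A `placement` stores where one query attaches to an edge-numbered
#' backbone tree: the chosen edge, how far along that edge (from the child,
#' i.e. leafward, end) the attachment point lies (`distal_length`), the
#' length of the query's own new branch (`pendant_length`), the optimized
#' log-likelihood, and the likelihood weight ratio of the chosen edge among
#' all candidate edges.
#'
#' @param query_name Query label.
#' @param edge_number Integer backbone edge number.
#' @param distal_length Distance from the child end of the edge (`>= 0`).
#' @param pendant_length Length of the query's pendant branch (`>= 0`).
#' @param log_likelihood Log-likelihood of the extended tree.
#' @param like_weight_ratio Normalized likelihood weight in `[0, 1]`.
#' @param per_edge_scores Optional named numeric vector of per-edge
#'   optimized log-likelihoods (names = edge numbers), kept for diagnostics.
#' @return An object of class `placement`.
#' @export
placement <- function(query_name, edge_number, distal_length, pendant_length,
                      log_likelihood, like_weight_ratio = 1,
                      per_edge_scores = NULL) {
  stopifnot(distal_length >= 0, pendant_length >= 0,
            like_weight_ratio >= 0, like_weight_ratio <= 1 + 1e-9)
  structure(list(query_name = query_name,
                 edge_number = as.integer(unname(edge_number)),
                 distal_length = unname(distal_length),
                 pendant_length = unname(pendant_length),
                 log_likelihood = unname(log_likelihood),
                 like_weight_ratio = unname(like_weight_ratio),
                 per_edge_scores = per_edge_scores),
            class = "placement")
}

#' @export
print.placement <- function(x, ...) {
  cat(sprintf("Placement of '%s': edge %d, distal %.6g, pendant %.6g, logL %.4f, LWR %.4f\n",
              x$query_name, x$edge_number, x$distal_length, x$pendant_length,
              x$log_likelihood, x$like_weight_ratio))
  invisible(x)
}

# Newick string with {edge_number} annotations after each branch length.
jplace_tree_string <- function(tree) {
  tree <- require_edge_numbers(tree)
  n <- length(tree$tip.label)
  kids <- children_list(tree)
  bl <- length_above(tree)
  enum <- integer(n + tree$Nnode)
  enum[tree$edge[, 2L]] <- tree$edge_number
  rec <- function(v) {
    core <- if (v <= n) tree$tip.label[v]
            else paste0("(", paste(vapply(kids[[v]], rec, ""), collapse = ","), ")")
    if (v == n + 1L) return(paste0(core, ";"))
    paste0(core, ":", format(bl[v], digits = 15, scientific = FALSE),
           "{", enum[v], "}")
  }
  rec(n + 1L)
}

#' Write placements to a jplace file
#'
#' Writes a jplace version 3 document with the standard five-field layout
#' `edge_num, likelihood, like_weight_ratio, distal_length, pendant_length`
#' and the backbone tree annotated with `{edge_number}` marks.
#'
#' @param tree Edge-numbered backbone `"phylo"` tree.
#' @param placements List of [placement()] objects (possibly empty).
#' @param path Output file path.
#' @param metadata Optional named list merged into the `metadata` object.
#' @return Invisibly, `path`.
#' @export
write_jplace <- function(tree, placements, path, metadata = list()) {
  tree <- require_edge_numbers(tree)
  if (inherits(placements, "placement")) placements <- list(placements)
  for (pl in placements) {
    if (!pl$edge_number %in% tree$edge_number) {
      stop("placement of '", pl$query_name, "' refers to unknown edge ",
           pl$edge_number)
    }
  }
  pl_entries <- lapply(placements, function(pl) {
    list(p = list(list(pl$edge_number, pl$log_likelihood,
                       pl$like_weight_ratio, pl$distal_length,
                       pl$pendant_length)),
         nm = list(list(pl$query_name, 1L)))
  })
  doc <- list(
    version = 3L,
    tree = jplace_tree_string(tree),
    placements = pl_entries,
    fields = list("edge_num", "likelihood", "like_weight_ratio",
                  "distal_length", "pendant_length"),
    metadata = c(list(invocation = "phyplace"), metadata))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read or write the model parameter file
#'
#' The model file is a flat JSON document with fields `exchangeabilities`
#' (6 reals: AC, AG, AT, CG, CT, GT), `base_freqs` (4 reals summing to 1),
#' `gamma_shape` (`> 0`) and `n_categories` (`>= 1`). `write` then `read`
#' round-trips all values exactly.
#'
#' @param path Path to the JSON model file.
#' @return For `parse_model_file`, a [gtr_gamma_model()] object.
#' @export
parse_model_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::fromJSON(path)
  for (f in c("exchangeabilities", "base_freqs", "gamma_shape", "n_categories")) {
    if (is.null(doc[[f]])) stop("model file missing field '", f, "'")
  }
  if (length(doc$exchangeabilities) != 6L) {
    stop("model file field 'exchangeabilities' must have 6 entries")
  }
  if (length(doc$base_freqs) != 4L) {
    stop("model file field 'base_freqs' must have 4 entries")
  }
  if (abs(sum(doc$base_freqs) - 1) > 1e-6) stop("frequencies must sum to 1")
  gtr_gamma_model(doc$exchangeabilities, doc$base_freqs,
                  alpha = doc$gamma_shape,
                  n_categories = as.integer(doc$n_categories))
}

#' @param model A `gtr_gamma` model to serialize.
#' @rdname parse_model_file
#' @export
write_model_file <- function(model, path) {
  stopifnot(inherits(model, "gtr_gamma"))
  doc <- list(exchangeabilities = unname(model$exchangeabilities),
              base_freqs = model$pi,
              gamma_shape = model$alpha,
              n_categories = model$n_categories)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
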