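# IUPAC nucleotide codes -> compatible states (A,C,G,T); gap/N/? are
# treated as fully missing downstream (all-ones leaf partial).
IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), `-` = c("A", "C", "G", "T"),
  `?` = c("A", "C", "G", "T"))

#' Create an aligned sequence set
#'
#' An `aligned_seqs` object is an ordered label -> sequence map over one
#' fixed column space: all sequences have the same length (the alignment
#' width `L`), labels are unique and non-empty, and the alphabet is
#' restricted to A, C, G, T, U, gap (`-`), `?`, N and the IUPAC ambiguity
#' codes. Sequences are stored upper-case.
#'
#' @param seqs Named character vector of aligned sequences.
#' @return An `aligned_seqs` object.
#' @export
aligned_seqs <- function(seqs) {
  if (length(seqs) == 0L) stop("alignment is empty")
  labels <- names(seqs)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("all sequences must have non-empty labels")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate sequence label: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  seqs <- toupper(as.character(seqs))
  names(seqs) <- labels
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- labels[lens != lens[1L]][1L]
    stop("ragged alignment: sequence '", bad, "' has length ",
         nchar(seqs[[bad]]), ", expected ", lens[1L])
  }
  allowed <- c(names(IUPAC_MAP))
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad <- setdiff(chars, allowed)
  if (length(bad) > 0L) {
    stop("invalid characters in alignment: ", paste(bad, collapse = " "))
  }
  structure(list(seqs = seqs, L = unname(lens[1L])), class = "aligned_seqs")
}

#' @export
print.aligned_seqs <- function(x, ...) {
  cat("Alignment: ", length(x$seqs), " sequences x ", x$L, " columns\n", sep = "")
  show <- utils::head(names(x$seqs), 5L)
  for (nm in show) {
    s <- x$seqs[[nm]]
    cat(sprintf("  %-12s %s%s\n", nm, substr(s, 1, min(50, nchar(s))),
                if (nchar(s) > 50) "..." else ""))
  }
  if (length(x$seqs) > 5L) cat("  ...\n")
  invisible(x)
}

#' @export
labels.aligned_seqs <- function(object, ...) names(object$seqs)

#' Read a FASTA alignment
#'
#' Parses a FASTA file into an [aligned_seqs()] object, preserving input
#' order, upper-casing sequences, and validating that all rows share one
#' alignment length.
#'
#' @param path Path to a FASTA file.
#' @return An `aligned_seqs` object.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("not a FASTA file (first line is not a header): ", path)
  idx <- cumsum(hdr)
  labels <- trimws(sub("^>\\s*", "", lines[hdr]))
  # first whitespace-delimited token is the label, pplacer-style
  labels <- sub("\\s.*$", "", labels)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, "", collapse = "")
  if (length(seqs) != length(labels)) {
    stop("FASTA record with no sequence lines in ", path)
  }
  names(seqs) <- labels
  aligned_seqs(gsub("\\s", "", seqs))
}

#' Write a FASTA alignment
#'
#' @param aln An `aligned_seqs` object.
#' @param path Output file path.
#' @param width Line-wrap width (default 80 columns).
#' @return Invisibly, `path`.
#' @export
write_fasta_alignment <- function(aln, path, width = 80L) {
  stopifnot(inherits(aln, "aligned_seqs"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(aln$seqs)) {
    writeLines(paste0(">", nm), con)
    s <- aln$seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Ungapped length of a sequence
#'
#' Number of non-gap characters of one aligned row; the "original" sequence
#' length of a query before alignment.
#'
#' @param aln An `aligned_seqs` object.
#' @param label Sequence label.
#' @return Integer count of non-`-` characters.
#' @export
ungapped_length <- function(aln, label) {
  s <- get_row(aln, label)
  nchar(gsub("-", "", s, fixed = TRUE))
}

get_row <- function(aln, label) {
  if (!label %in% names(aln$seqs)) stop("no sequence named '", label, "'")
  aln$seqs[[label]]
}

# Subset rows, keeping order of `labels`.
subset_alignment <- function(aln, labels) {
  missing <- setdiff(labels, names(aln$seqs))
  if (length(missing) > 0L) {
    stop("labels not in alignment: ", paste(missing, collapse = ", "))
  }
  structure(list(seqs = aln$seqs[labels], L = aln$L), class = "aligned_seqs")
}

# Character matrix view (rows = sequences); cached per call site.
alignment_matrix <- function(aln) {
  m <- matrix("", nrow = length(aln$seqs), ncol = aln$L,
              dimnames = list(names(aln$seqs), NULL))
  sp <- strsplit(aln$seqs, "")
  for (i in seq_along(sp)) m[i, ] <- sp[[i]]
  m
}

# 4 x L leaf partial-likelihood matrix for one aligned row.
leaf_partials <- function(seq_string) {
  chars <- strsplit(seq_string, "")[[1]]
  out <- matrix(0, nrow = 4L, ncol = length(chars))
  for (code in unique(chars)) {
    states <- IUPAC_MAP[[code]]
    out[match(states, DNA_STATES), chars == code] <- 1
  }
  out
}
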