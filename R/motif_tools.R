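# Position frequency matrix utilities: JASPAR I/O, a column-correlation
# distance over ungapped offsets (both strands), and greedy redundancy
# reduction of a motif collection.

#' Position frequency matrix
#'
#' @param motif_id motif identifier.
#' @param counts 4 x L numeric matrix of non-negative base frequencies, rows
#'   A, C, G, T; L >= 3.
#' @return An object of class `PositionFrequencyMatrix`.
#' @export
pfm <- function(motif_id, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stopf("a PFM needs 4 rows (A, C, G, T)")
  if (ncol(counts) < 3) stopf("PFM '%s' shorter than 3 columns", motif_id)
  if (any(counts < 0) || anyNA(counts)) stopf("PFM frequencies must be non-negative")
  if (any(colSums(counts) <= 0)) stopf("PFM '%s' has an all-zero column", motif_id)
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(motif_id = as.character(motif_id), counts = counts),
            class = "PositionFrequencyMatrix")
}

#' @export
print.PositionFrequencyMatrix <- function(x, ...) {
  cat(sprintf("PFM %s (length %d)\n", x$motif_id, ncol(x$counts)))
  invisible(x)
}

pfm_length <- function(x) ncol(x$counts)

# Column-normalize so every column sums to 1.
pfm_probs <- function(x) sweep(x$counts, 2, colSums(x$counts), "/")

#' Read / write JASPAR-format PFM files
#'
#' The JASPAR text format: a `>id name` header line followed by four rows
#' `A [ 1 2 3 ]` etc.
#'
#' @param path file path.
#' @return `read_jaspar()` returns a named list of
#'   [pfm()] objects.
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  if (length(headers) == 0) stopf("no '>' headers in %s", path)
  out <- lapply(seq_along(headers), function(i) {
    start <- headers[i]
    id <- strsplit(sub("^>", "", lines[start]), "\\s+")[[1]][1]
    rows <- lines[(start + 1):(start + 4)]
    parse_row <- function(r) {
      body <- sub("^[ACGTacgt]", "", r)
      as.numeric(regmatches(body, gregexpr("[0-9.eE+-]+", body))[[1]])
    }
    counts <- t(vapply(rows, parse_row, numeric(length(parse_row(rows[1])))))
    pfm(id, counts)
  })
  stats::setNames(out, vapply(out, `[[`, "", "motif_id"))
}

#' @rdname read_jaspar
#' @param pfms list of [pfm()] objects.
#' @export
write_jaspar <- function(pfms, path) {
  lines <- unlist(lapply(pfms, function(p) {
    c(paste0(">", p$motif_id, " ", p$motif_id),
      vapply(1:4, function(r) {
        paste0(c("A", "C", "G", "T")[r], " [ ",
               paste(format(p$counts[r, ], trim = TRUE), collapse = " "), " ]")
      }, ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Distance between two position frequency matrices
#'
#' One minus the best ungapped alignment score between the two
#' column-normalized matrices, where the score of an alignment is the mean
#' per-column Pearson correlation between aligned columns. All offsets with
#' at least `min_overlap` aligned columns are considered, for `b` in forward
#' orientation and reverse-complemented (columns reversed, A/T and C/G rows
#' swapped). The result is clamped to \[0,1\]; identical matrices at full
#' overlap give 0.
#'
#' A zero-variance column (uniform base frequencies) has no defined Pearson
#' correlation; a pair of such columns contributes 1 when the normalized
#' columns are equal and 0 otherwise, and a mixed pair contributes 0.
#'
#' @param a,b [pfm()] objects.
#' @param min_overlap minimum aligned columns (>= 3, <= both lengths).
#' @return distance in \[0, 1\]; symmetric in its arguments.
#' @export
pfm_distance <- function(a, b, min_overlap = 4) {
  la <- pfm_length(a); lb <- pfm_length(b)
  if (min_overlap < 3) stopf("min_overlap must be >= 3")
  if (min_overlap > min(la, lb)) {
    stopf("motif shorter than min_overlap (%d vs %d)", min(la, lb), min_overlap)
  }
  pa <- pfm_probs(a)
  pb_fwd <- pfm_probs(b)
  pb_rc <- pb_fwd[4:1, lb:1, drop = FALSE]
  best <- -Inf
  for (pb in list(pb_fwd, pb_rc)) {
    for (s in seq(-(lb - min_overlap), la - min_overlap)) {
      ia <- max(1, 1 + s):min(la, lb + s)
      ib <- ia - s
      cors <- vapply(seq_along(ia), function(j) {
        column_cor(pa[, ia[j]], pb[, ib[j]])
      }, numeric(1))
      best <- max(best, mean(cors))
    }
  }
  min(1, max(0, 1 - best))
}

column_cor <- function(u, v) {
  su <- stats::sd(u); sv <- stats::sd(v)
  if (su == 0 && sv == 0) return(if (isTRUE(all.equal(u, v))) 1 else 0)
  if (su == 0 || sv == 0) return(0)
  stats::cor(u, v)
}

#' Reduce a motif collection to a non-redundant set
#'
#' Greedy elimination: repeatedly find the globally most similar pair of
#' motifs; while that pair's distance is below `threshold`, remove the longer
#' of the two (equal lengths: remove the lexicographically later motif id).
#' All retained pairwise distances end up >= `threshold`.
#'
#' @param pfms list of [pfm()] objects.
#' @param threshold distance below which a pair is considered redundant.
#' @param distance distance function taking two PFMs (pluggable; default
#'   [pfm_distance()]).
#' @param min_overlap passed to the default distance.
#' @return the retained subset of `pfms`, in input order.
#' @export
reduce_redundant_motifs <- function(pfms, threshold = 0.3,
                                    distance = pfm_distance, min_overlap = 4) {
  if (length(pfms) == 0) stopf("need at least one motif")
  ids <- vapply(pfms, `[[`, "", "motif_id")
  assert_no_duplicates(ids, "motif ids")
  n <- length(pfms)
  if (n == 1) return(pfms)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- if (identical(distance, pfm_distance)) {
        distance(pfms[[i]], pfms[[j]], min_overlap)
      } else distance(pfms[[i]], pfms[[j]])
    }
  }
  lens <- vapply(pfms, pfm_length, integer(1))
  alive <- rep(TRUE, n)
  while (sum(alive) > 1) {
    idx <- which(alive)
    sub <- D[idx, idx, drop = FALSE]
    dmin <- min(sub)
    if (dmin >= threshold) break
    # among minimal pairs, pick the lexicographically smallest sorted id pair
    hits <- which(sub <= dmin + 1e-15 & upper.tri(sub), arr.ind = TRUE)
    keys <- apply(hits, 1, function(h) {
      paste(sort(c(ids[idx[h[1]]], ids[idx[h[2]]])), collapse = "\r")
    })
    h <- hits[order(keys)[1], ]
    i <- idx[h[1]]; j <- idx[h[2]]
    drop <- if (lens[i] != lens[j]) {
      if (lens[i] > lens[j]) i else j
    } else if (ids[i] > ids[j]) i else j
    alive[drop] <- FALSE
  }
  pfms[alive]
}

#' @rdname reduce_redundant_motifs
#' @param path output path; retained motif ids are written one per line.
#' @export
write_motif_ids <- function(pfms, path) {
  writeLines(vapply(pfms, `[[`, "", "motif_id"), path)
  invisible(path)
}
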