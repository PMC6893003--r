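# Sequence reduction: rewriting natural protein sequences over a scheme's
# cluster representatives, and natural<->reduced correspondence statistics.

# Splits a sequence string into an upper-cased character vector of residues.
residue_vector <- function(seq) {
  strsplit(toupper(as.character(seq)), "")[[1]]
}

#' Reduce a protein sequence to a scheme's representative alphabet
#'
#' Each standard residue is replaced by the representative letter of its
#' cluster. Residues outside the 20 standard codes (e.g. B, Z, X, U, O) are
#' handled by `unknown_policy`:
#' \describe{
#'   \item{mask}{(default) keep position, write `X`, flag it in the mask;}
#'   \item{drop}{remove the position (original indices of kept positions
#'     are returned in `kept_positions`);}
#'   \item{error}{abort, naming the first offending position and character.}
#' }
#' Input is case-insensitive; output is upper-case. Positions in messages
#' and bookkeeping are 1-based.
#'
#' @param seq a residue string (a single sequence).
#' @param scheme a [raac_scheme()].
#' @param unknown_policy one of `"mask"`, `"drop"`, `"error"`.
#' @return a `raac_reduced` object: list with `id` (if `seq` was named),
#'   `residues` (the reduced string), `mask` (logical, `TRUE` where the
#'   source residue was non-standard; always source length under `mask`
#'   policy), `kept_positions` (under `drop`), and `scheme_key`.
#' @examples
#' sch <- raac_scheme("t2", 2, c("ARNDQEGHKPST", "CILMFWYV"))
#' reduce_sequence("ACDW", sch)$residues  # "ACAC"
#' @export
reduce_sequence <- function(seq, scheme,
                            unknown_policy = c("mask", "drop", "error")) {
  unknown_policy <- match.arg(unknown_policy)
  stopifnot(inherits(scheme, "raac_scheme"))
  id <- if (!is.null(names(seq))) names(seq)[1] else NA_character_
  res <- residue_vector(seq)
  if (length(res) == 0L) stop("empty sequence", call. = FALSE)
  map <- scheme_mapping(scheme)
  std <- res %in% AA20
  if (!all(std)) {
    bad_pos <- which(!std)
    if (unknown_policy == "error") {
      stop(sprintf("non-standard residue '%s' at position %d%s",
                   res[bad_pos[1]], bad_pos[1],
                   if (is.na(id)) "" else paste0(" in ", id)),
           call. = FALSE)
    }
  }
  if (unknown_policy == "drop") {
    kept <- which(std)
    if (length(kept) == 0L) {
      stop("sequence empty after dropping non-standard residues",
           call. = FALSE)
    }
    out <- map[res[kept]]
    return(structure(
      list(id = id, residues = paste(out, collapse = ""),
           mask = rep(FALSE, length(kept)), kept_positions = kept,
           scheme_key = c(scheme$type_id, scheme$size)),
      class = "raac_reduced"
    ))
  }
  out <- character(length(res))
  out[std] <- map[res[std]]
  out[!std] <- "X"
  structure(
    list(id = id, residues = paste(out, collapse = ""), mask = !std,
         kept_positions = seq_along(res),
         scheme_key = c(scheme$type_id, scheme$size)),
    class = "raac_reduced"
  )
}

#' @export
print.raac_reduced <- function(x, ...) {
  cat(sprintf("reduced sequence%s [%s size %s], %d aa, %d masked\n%s\n",
              if (is.na(x$id)) "" else paste0(" ", x$id),
              x$scheme_key[1], x$scheme_key[2],
              nchar(x$residues), sum(x$mask), x$residues))
  invisible(x)
}

#' Natural-to-representative mergence table
#'
#' Tabulates, over a set of sequences, how often each natural residue flows
#' into each cluster representative — the quantitative backbone of a
#' Sankey-style "mergence" view where line width is proportional to residue
#' frequency. Non-standard residues are excluded from the counts.
#'
#' @param seqs character vector of residue strings (optionally named).
#' @param scheme a [raac_scheme()].
#' @return data frame with columns `natural`, `representative`, `count`,
#'   `frequency`; frequencies sum to 1 over the table.
#' @export
mergence_table <- function(seqs, scheme) {
  stopifnot(inherits(scheme, "raac_scheme"))
  res <- unlist(lapply(seqs, residue_vector), use.names = FALSE)
  res <- res[res %in% AA20]
  if (length(res) == 0L) {
    stop("no standard residues in input sequences", call. = FALSE)
  }
  map <- scheme_mapping(scheme)
  counts <- table(factor(res, levels = AA20))
  present <- names(counts)[counts > 0L]
  df <- data.frame(
    natural = present,
    representative = unname(map[present]),
    count = as.integer(counts[present]),
    stringsAsFactors = FALSE
  )
  df$frequency <- df$count / sum(df$count)
  # order rows by cluster order then natural letter, matching the scheme
  cluster_rank <- match(df$representative, scheme$representative)
  df <- df[order(cluster_rank, df$natural), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Paired natural and reduced amino acid composition
#'
#' Computes the 20-bin natural amino acid composition and the R-bin reduced
#' composition of a sequence set. The reduced bin of cluster r equals the
#' sum of the natural bins of its member residues.
#'
#' @inheritParams mergence_table
#' @return list with `natural` (named numeric, 20 bins in canonical residue
#'   order) and `reduced` (named numeric, R bins in cluster order); each
#'   sums to 1.
#' @export
composition_distribution <- function(seqs, scheme) {
  stopifnot(inherits(scheme, "raac_scheme"))
  res <- unlist(lapply(seqs, residue_vector), use.names = FALSE)
  res <- res[res %in% AA20]
  if (length(res) == 0L) {
    stop("no standard residues in input sequences", call. = FALSE)
  }
  natural <- as.numeric(table(factor(res, levels = AA20))) / length(res)
  names(natural) <- AA20
  reduced <- vapply(scheme$clusters, function(cl) {
    sum(natural[strsplit(cl, "")[[1]]])
  }, numeric(1))
  names(reduced) <- scheme$representative
  list(natural = natural, reduced = reduced)
}
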