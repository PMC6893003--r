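# K-tuple reduced amino acid composition under the three correlation
# parameters: K (tuple size), g (gap between successive windows), lambda
# (spacing between adjacent residues inside a window).

#' Construct a tuple specification
#'
#' The triple (K, g, lambda) governs window enumeration:
#' \itemize{
#'   \item K residues are taken per window;
#'   \item adjacent residues within a window are `lambda` positions apart
#'     beyond contiguity (index stride `lambda + 1`); `lambda = 0` means a
#'     contiguous K-mer, `K = 2, lambda = 2` captures CxxC-style motifs;
#'   \item successive window start positions differ by `g + 1`; `g = 0`
#'     gives fully overlapping windows.
#' }
#' A window starting at s covers positions s, s+(lambda+1), ...,
#' s+(K-1)(lambda+1), so the window span is `(K-1)(lambda+1) + 1` and a
#' sequence of length L yields `floor((L - span)/(g+1)) + 1` windows when
#' L >= span, else none.
#'
#' @param K integer tuple size >= 1 (1 = monopeptide, 2 = dipeptide, ...).
#' @param g integer inter-window gap >= 0.
#' @param lam integer intra-window spacing >= 0.
#' @return a `tuple_spec` object with fields `K`, `g`, `lam`, `span`.
#' @examples
#' tuple_spec(3, g = 2, lam = 1)$span  # 5
#' @export
tuple_spec <- function(K = 2L, g = 0L, lam = 0L) {
  K <- as.integer(K); g <- as.integer(g); lam <- as.integer(lam)
  if (is.na(K) || K < 1L) stop("K must be an integer >= 1", call. = FALSE)
  if (is.na(g) || g < 0L) stop("g must be an integer >= 0", call. = FALSE)
  if (is.na(lam) || lam < 0L) stop("lam must be an integer >= 0", call. = FALSE)
  structure(list(K = K, g = g, lam = lam,
                 span = (K - 1L) * (lam + 1L) + 1L),
            class = "tuple_spec")
}

#' @export
print.tuple_spec <- function(x, ...) {
  cat(sprintf("tuple spec: K=%d g=%d lambda=%d (span %d)\n",
              x$K, x$g, x$lam, x$span))
  invisible(x)
}

#' Enumerate K-tuple windows over a sequence of length L
#'
#' Returns the 1-based residue positions of every window: row w holds
#' `(s, s+(lam+1), ..., s+(K-1)(lam+1))` for start `s = 1, 1+(g+1),
#' 1+2(g+1), ...` as long as the last index stays within L. With K=2, g=0
#' this walks R1R2, R2R3, R3R4, ...; with K=2, g=1 it walks R1R2, R3R4,
#' R5R6, ...; with K=3, g=2, lambda=1 it walks R1R3R5, R4R6R8, R7R9R11.
#'
#' @param L sequence length (>= 1).
#' @param spec a [tuple_spec()].
#' @return integer matrix with K columns, one row per window (0 rows when
#'   L < span).
#' @export
enumerate_windows <- function(L, spec) {
  stopifnot(inherits(spec, "tuple_spec"))
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("L must be an integer >= 1", call. = FALSE)
  if (L < spec$span) {
    return(matrix(integer(0), nrow = 0L, ncol = spec$K))
  }
  starts <- seq.int(1L, L - spec$span + 1L, by = spec$g + 1L)
  offsets <- (seq_len(spec$K) - 1L) * (spec$lam + 1L)
  outer(starts, offsets, `+`)
}

#' Column labels of the reduced K-tuple feature space
#'
#' All R^K tuples over the scheme's representative letters, ordered as the
#' lexicographic product of the scheme's cluster order (first tuple
#' position most significant). This ordering — not alphabetical — keeps
#' feature columns aligned with the scheme file's own cluster ordering and
#' is deterministic across runs.
#'
#' @param scheme a [raac_scheme()].
#' @param K tuple size.
#' @return character vector of length `scheme$size ^ K`.
#' @export
tuple_labels <- function(scheme, K) {
  stopifnot(inherits(scheme, "raac_scheme"))
  K <- as.integer(K)
  R <- scheme$size
  n <- R^K
  if (n > 2^22) stop("R^K too large (", n, " columns)", call. = FALSE)
  j <- seq_len(n) - 1L
  lab <- rep("", n)
  for (p in seq_len(K)) {
    digit <- (j %/% R^(K - p)) %% R
    lab <- paste0(lab, scheme$representative[digit + 1L])
  }
  lab
}

# Maps a residue vector to cluster indices (1..R); non-standard residues
# become NA under "mask", are removed under "drop", abort under "error".
cluster_indices <- function(res, scheme, unknown_policy) {
  lookup <- integer(20)
  names(lookup) <- AA20
  for (i in seq_along(scheme$clusters)) {
    lookup[strsplit(scheme$clusters[i], "")[[1]]] <- i
  }
  idx <- unname(lookup[res])   # NA for residues outside AA20
  if (anyNA(idx)) {
    if (unknown_policy == "error") {
      p <- which(is.na(idx))[1]
      stop(sprintf("non-standard residue '%s' at position %d", res[p], p),
           call. = FALSE)
    }
    if (unknown_policy == "drop") idx <- idx[!is.na(idx)]
  }
  idx
}

#' K-tuple reduced amino acid composition of one sequence
#'
#' Maps every enumerated window through the scheme and counts the reduced
#' tuples it spells, then normalizes by the number of counted windows so
#' the result lies on the R^K simplex. Under the `mask` policy, windows
#' touching a non-standard residue are skipped (they do not enter the
#' denominator); under `drop`, non-standard residues are removed before
#' enumeration; under `error`, any non-standard residue aborts.
#'
#' @param seq a residue string.
#' @param scheme a [raac_scheme()].
#' @param spec a [tuple_spec()].
#' @param unknown_policy one of `"mask"`, `"drop"`, `"error"`.
#' @return named numeric vector of length R^K (names from
#'   [tuple_labels()]), with attributes `window_count` (windows counted)
#'   and `skipped` (windows skipped for masked residues).
#' @examples
#' sch <- raac_scheme("t2", 2, c("ARNDQEGHKPST", "CILMFWYV"))
#' ktuple_composition("ACAC", sch, tuple_spec(2, g = 1))
#' @export
ktuple_composition <- function(seq, scheme, spec = tuple_spec(),
                               unknown_policy = c("mask", "drop", "error")) {
  unknown_policy <- match.arg(unknown_policy)
  stopifnot(inherits(scheme, "raac_scheme"), inherits(spec, "tuple_spec"))
  res <- residue_vector(seq)
  idx <- cluster_indices(res, scheme, unknown_policy)
  L <- length(idx)
  R <- scheme$size
  labels <- tuple_labels(scheme, spec$K)
  win <- if (L >= 1L) enumerate_windows(L, spec) else
    matrix(integer(0), 0L, spec$K)
  skipped <- 0L
  vec <- numeric(length(labels))
  names(vec) <- labels
  if (nrow(win) > 0L) {
    m <- matrix(idx[win], nrow = nrow(win))  # cluster index per window slot
    ok <- rowSums(is.na(m)) == 0L
    skipped <- sum(!ok)
    m <- m[ok, , drop = FALSE]
    if (nrow(m) > 0L) {
      weights <- R^((spec$K - 1L):0L)
      codes <- as.integer((m - 1L) %*% weights) + 1L
      vec <- tabulate(codes, nbins = length(labels)) / nrow(m)
      names(vec) <- labels
    }
  }
  n_counted <- if (nrow(win) > 0L) nrow(win) - skipped else 0L
  if (n_counted == 0L) {
    stop(sprintf(paste0("no extractable windows: length %d, window span %d",
                        ", %d window(s) skipped for masked residues"),
                 L, spec$span, skipped), call. = FALSE)
  }
  attr(vec, "window_count") <- n_counted
  attr(vec, "skipped") <- skipped
  vec
}

#' Extract a K-tuple RAAC feature matrix from a sequence set
#'
#' Applies [ktuple_composition()] to each sequence. Sequences yielding no
#' countable window (shorter than the window span, or fully masked) are
#' dropped with a warning and listed in the `rejects` field.
#'
#' @param seqs named character vector of residue strings (names are
#'   sequence ids; unnamed input gets `seq1, seq2, ...`).
#' @inheritParams ktuple_composition
#' @return a `raac_features` object: list with `matrix` (rows = sequences,
#'   columns = R^K tuple labels; each row sums to 1), `row_ids`, `spec`,
#'   `scheme_key`, `window_counts`, `rejects` (data frame id/reason).
#' @export
extract_features <- function(seqs, scheme, spec = tuple_spec(),
                             unknown_policy = c("mask", "drop", "error")) {
  unknown_policy <- match.arg(unknown_policy)
  stopifnot(inherits(scheme, "raac_scheme"), inherits(spec, "tuple_spec"))
  if (length(seqs) == 0L) stop("no input sequences", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  labels <- tuple_labels(scheme, spec$K)
  rows <- vector("list", length(seqs))
  wc <- integer(length(seqs))
  rejects <- data.frame(id = character(0), reason = character(0))
  for (i in seq_along(seqs)) {
    row <- tryCatch(
      ktuple_composition(seqs[[i]], scheme, spec, unknown_policy),
      error = function(e) e
    )
    if (inherits(row, "error")) {
      rejects <- rbind(rejects,
                       data.frame(id = ids[i], reason = conditionMessage(row)))
      rows[i] <- list(NULL)
    } else {
      wc[i] <- attr(row, "window_count")
      rows[[i]] <- as.numeric(row)
    }
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) {
    stop("all sequences rejected during feature extraction", call. = FALSE)
  }
  if (nrow(rejects) > 0L) {
    warning("dropped ", nrow(rejects), " sequence(s) with no extractable ",
            "windows: ", paste(rejects$id, collapse = ", "), call. = FALSE)
  }
  mat <- do.call(rbind, rows[keep])
  dimnames(mat) <- list(ids[keep], labels)
  structure(
    list(matrix = mat, row_ids = ids[keep], spec = spec,
         scheme_key = c(scheme$type_id, scheme$size),
         window_counts = wc[keep], rejects = rejects),
    class = "raac_features"
  )
}

#' @export
print.raac_features <- function(x, ...) {
  cat(sprintf(paste0("RAAC feature matrix: %d sequence(s) x %d tuple ",
                     "column(s) [%s size %s, K=%d g=%d lambda=%d]\n"),
              nrow(x$matrix), ncol(x$matrix), x$scheme_key[1],
              x$scheme_key[2], x$spec$K, x$spec$g, x$spec$lam))
  if (nrow(x$rejects) > 0L) {
    cat(sprintf("  %d sequence(s) rejected\n", nrow(x$rejects)))
  }
  invisible(x)
}

#' Write a feature matrix as CSV
#'
#' First column `id`, then the R^K tuple columns with a mandatory header
#' row; frequencies are serialized with full double round-trip precision.
#'
#' @param features a `raac_features` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  stopifnot(inherits(features, "raac_features"))
  m <- features$matrix
  header <- paste(c("id", colnames(m)), collapse = ",")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], digits = 17, trim = TRUE,
                                   scientific = FALSE)),
          collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a feature matrix in sparse libsvm format
#'
#' One line per sequence: `<label> <index>:<value> ...` with 1-based
#' indices in column order and zero entries omitted.
#'
#' @param features a `raac_features` object.
#' @param path output file path.
#' @param labels optional numeric labels, one per row (defaults to 0).
#' @return `path`, invisibly.
#' @export
write_features_libsvm <- function(features, path, labels = NULL) {
  stopifnot(inherits(features, "raac_features"))
  m <- features$matrix
  if (is.null(labels)) labels <- rep(0, nrow(m))
  stopifnot(length(labels) == nrow(m))
  lines <- vapply(seq_len(nrow(m)), function(i) {
    nz <- which(m[i, ] != 0)
    paste(c(format(labels[i], trim = TRUE),
            paste0(nz, ":", format(m[i, nz], digits = 17, trim = TRUE,
                                   scientific = FALSE))),
          collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
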