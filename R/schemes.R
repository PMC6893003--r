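#' Construct a reduction scheme
#'
#' A reduction scheme is one named partition of the 20 standard amino acids
#' into `size` clusters. Each cluster is written as a string of one-letter
#' residue codes; the cluster's representative letter is its first residue
#' as written, and reduced sequences are spelled over these representatives.
#'
#' @param type_id character label of the alphabet family (e.g. `"t1"`).
#' @param size integer number of clusters R, with 2 <= R <= 20 (R = 20 is
#'   the identity alphabet).
#' @param clusters character vector of `size` non-empty strings over the 20
#'   standard one-letter codes, jointly a disjoint exhaustive partition.
#' @param source free-text description or citation for the scheme.
#' @return an object of class `raac_scheme` with fields `type_id`, `size`,
#'   `clusters`, `representative`, `source`.
#' @examples
#' sch <- raac_scheme("t2", 2, c("ARNDQEGHKPST", "CILMFWYV"))
#' sch$representative  # "A" "C"
#' @export
raac_scheme <- function(type_id, size, clusters, source = "") {
  stopifnot(is.character(type_id), length(type_id) == 1L, nzchar(type_id))
  size <- as.integer(size)
  clusters <- toupper(as.character(clusters))
  problems <- validate_partition(clusters)
  if (!is.null(problems)) {
    stop("invalid scheme '", type_id, "' size ", size, ": ", problems,
         call. = FALSE)
  }
  if (length(clusters) != size) {
    stop("invalid scheme '", type_id, "': declared size ", size,
         " but ", length(clusters), " clusters given", call. = FALSE)
  }
  structure(
    list(
      type_id = type_id,
      size = size,
      clusters = clusters,
      representative = substr(clusters, 1L, 1L),
      source = as.character(source)
    ),
    class = "raac_scheme"
  )
}

# Returns NULL if `clusters` is a valid partition of the 20 standard
# residues, else a human-readable description of what is wrong.
validate_partition <- function(clusters) {
  if (length(clusters) < 1L || any(!nzchar(clusters))) {
    return("empty cluster present")
  }
  letters_all <- unlist(strsplit(clusters, ""))
  bad <- setdiff(letters_all, AA20)
  if (length(bad) > 0L) {
    return(paste0("non-standard letters: ", paste(sort(unique(bad)), collapse = "")))
  }
  tab <- table(factor(letters_all, levels = AA20))
  dup <- names(tab)[tab > 1L]
  mis <- names(tab)[tab == 0L]
  msg <- character(0)
  if (length(dup) > 0L) {
    msg <- c(msg, paste0("duplicated residues: ", paste(dup, collapse = "")))
  }
  if (length(mis) > 0L) {
    msg <- c(msg, paste0("missing residues (", length(mis), "): ",
                         paste(mis, collapse = "")))
  }
  if (length(msg) > 0L) paste(msg, collapse = "; ") else NULL
}

#' @export
print.raac_scheme <- function(x, ...) {
  cat(sprintf("RAAC scheme %s, %d clusters: %s\n",
              x$type_id, x$size, paste(x$clusters, collapse = "-")))
  invisible(x)
}

#' Parse a scheme table from text
#'
#' Parses the flat tab-separated registry format: a header line
#' `type<TAB>size<TAB>clusters<TAB>source`, then one scheme per line with
#' the clusters column written `GROUP1-GROUP2-...`. Lines starting with `#`
#' and blank lines are ignored. Input residue letters are upper-cased
#' before validation. The `source` column is optional per line.
#'
#' @param text character scalar (or vector of lines) with the table content.
#' @param strict logical; if `TRUE` (default) any malformed or invalid line
#'   aborts with an error naming the offending line numbers, if `FALSE`
#'   such lines are dropped with a warning and listed in the result's
#'   `rejects` attribute.
#' @return an object of class `raac_registry`: a list with `schemes` (named
#'   list of [raac_scheme()] objects keyed `"type_id|size"`).
#' @examples
#' reg <- parse_scheme_table("type\tsize\tclusters\tsource\nt2\t2\tARNDQEGHKPST-CILMFWYV\tdemo")
#' length(reg$schemes)
#' @export
parse_scheme_table <- function(text, strict = TRUE) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  if (length(text) == 0L || all(!nzchar(trimws(text)))) {
    stop("empty scheme table", call. = FALSE)
  }
  lineno <- seq_along(text)
  keep <- nzchar(trimws(text)) & !startsWith(trimws(text), "#")
  text <- text[keep]
  lineno <- lineno[keep]
  # drop the header if present
  if (length(text) > 0L && grepl("^type\t", text[1])) {
    text <- text[-1]
    lineno <- lineno[-1]
  }
  if (length(text) == 0L) stop("scheme table has no data lines", call. = FALSE)

  schemes <- list()
  rejects <- data.frame(line = integer(0), reason = character(0))
  for (i in seq_along(text)) {
    fields <- strsplit(text[i], "\t", fixed = TRUE)[[1]]
    reason <- NULL
    if (length(fields) < 3L) {
      reason <- sprintf("line %d: expected at least 3 tab-separated columns, got %d",
                        lineno[i], length(fields))
    } else {
      type_id <- trimws(fields[1])
      size <- suppressWarnings(as.integer(trimws(fields[2])))
      clusters <- strsplit(toupper(trimws(fields[3])), "-", fixed = TRUE)[[1]]
      source <- if (length(fields) >= 4L) trimws(fields[4]) else ""
      if (!nzchar(type_id) || is.na(size)) {
        reason <- sprintf("line %d: malformed type/size columns", lineno[i])
      } else if (!is.null(p <- validate_partition(clusters))) {
        reason <- sprintf("line %d: %s", lineno[i], p)
      } else if (length(clusters) != size) {
        reason <- sprintf("line %d: declared size %d but %d clusters",
                          lineno[i], size, length(clusters))
      } else {
        key <- paste(type_id, size, sep = "|")
        if (!is.null(schemes[[key]])) {
          reason <- sprintf("line %d: duplicate scheme key (%s, %d)",
                            lineno[i], type_id, size)
        } else {
          schemes[[key]] <- raac_scheme(type_id, size, clusters, source)
        }
      }
    }
    if (!is.null(reason)) {
      rejects <- rbind(rejects, data.frame(line = lineno[i], reason = reason))
    }
  }
  if (nrow(rejects) > 0L) {
    if (strict) {
      stop("scheme table parse failed:\n  ",
           paste(rejects$reason, collapse = "\n  "), call. = FALSE)
    }
    warning("dropped ", nrow(rejects), " invalid scheme line(s): ",
            paste(rejects$line, collapse = ", "), call. = FALSE)
  }
  if (length(schemes) == 0L) stop("no valid schemes in table", call. = FALSE)
  structure(list(schemes = schemes, rejects = rejects),
            class = "raac_registry")
}

#' Read a scheme table file
#'
#' @param path path to a scheme table in the tab-separated registry format
#'   (see [parse_scheme_table()]).
#' @param strict see [parse_scheme_table()].
#' @return a `raac_registry`.
#' @export
read_scheme_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("scheme table not found: ", path, call. = FALSE)
  parse_scheme_table(readLines(path, warn = FALSE), strict = strict)
}

#' Serialize a registry back to scheme-table text
#'
#' Inverse of [parse_scheme_table()]: `parse_scheme_table(serialize_scheme_table(reg))`
#' reproduces the registry.
#'
#' @param registry a `raac_registry`.
#' @return character vector of lines (header first).
#' @export
serialize_scheme_table <- function(registry) {
  stopifnot(inherits(registry, "raac_registry"))
  rows <- vapply(registry$schemes, function(s) {
    paste(s$type_id, s$size, paste(s$clusters, collapse = "-"), s$source,
          sep = "\t")
  }, character(1))
  c("type\tsize\tclusters\tsource", unname(rows))
}

#' Write a registry to a scheme-table file
#' @param registry a `raac_registry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scheme_table <- function(registry, path) {
  writeLines(serialize_scheme_table(registry), path)
  invisible(path)
}

#' @export
print.raac_registry <- function(x, ...) {
  types <- unique(vapply(x$schemes, `[[`, character(1), "type_id"))
  cat(sprintf("RAAC registry: %d schemes across %d type families\n",
              length(x$schemes), length(types)))
  invisible(x)
}

# Numeric-aware ordering key for type ids: "t2" < "t11".
type_order_key <- function(type_ids) {
  num <- suppressWarnings(as.numeric(sub("^.*?(\\d+)$", "\\1", type_ids)))
  num[!grepl("\\d$", type_ids)] <- NA
  order(is.na(num), num, type_ids)
}

#' Filter schemes in a registry
#'
#' Selects schemes matching every provided criterion (conjunctive). Schemes
#' are returned in canonical order: type family (numeric on any trailing
#' integer, so `"t2"` sorts before `"t11"`), then cluster size.
#'
#' @param registry a `raac_registry`.
#' @param type_id optional type family label to match exactly.
#' @param size optional cluster count to match.
#' @param keyword optional case-insensitive substring matched against the
#'   `type_id` and `source` fields.
#' @return a list of `raac_scheme` objects (possibly empty).
#' @export
filter_schemes <- function(registry, type_id = NULL, size = NULL,
                           keyword = NULL) {
  stopifnot(inherits(registry, "raac_registry"))
  out <- unname(registry$schemes)
  if (!is.null(type_id)) {
    out <- Filter(function(s) s$type_id == type_id, out)
  }
  if (!is.null(size)) {
    size <- as.integer(size)
    out <- Filter(function(s) s$size == size, out)
  }
  if (!is.null(keyword)) {
    out <- Filter(function(s) {
      grepl(keyword, paste(s$type_id, s$source), ignore.case = TRUE,
            fixed = FALSE)
    }, out)
  }
  if (length(out) == 0L) return(list())
  tid <- vapply(out, `[[`, character(1), "type_id")
  sz <- vapply(out, `[[`, integer(1), "size")
  # order by type family first (numeric-aware), then size
  fam_levels <- unique(tid)[type_order_key(unique(tid))]
  out[order(match(tid, fam_levels), sz)]
}

#' Look up one scheme by type and size
#'
#' @inheritParams filter_schemes
#' @return a single `raac_scheme`; errors if absent.
#' @export
get_scheme <- function(registry, type_id, size) {
  stopifnot(inherits(registry, "raac_registry"))
  key <- paste(type_id, as.integer(size), sep = "|")
  s <- registry$schemes[[key]]
  if (is.null(s)) {
    stop("no scheme (", type_id, ", ", size, ") in registry", call. = FALSE)
  }
  s
}

#' Residue-to-representative substitution map
#'
#' Materializes a scheme's partition as a 20-entry named character vector
#' mapping each standard residue to the representative letter of its
#' cluster. The map is idempotent: representatives map to themselves.
#'
#' @param scheme a `raac_scheme`.
#' @return named character vector of length 20 (names = residues).
#' @examples
#' scheme_mapping(identity_scheme())[["W"]]  # "W"
#' @export
scheme_mapping <- function(scheme) {
  stopifnot(inherits(scheme, "raac_scheme"))
  map <- character(20)
  names(map) <- AA20
  for (i in seq_along(scheme$clusters)) {
    members <- strsplit(scheme$clusters[i], "")[[1]]
    map[members] <- scheme$representative[i]
  }
  map
}

#' The 20-cluster identity scheme
#'
#' Each residue is its own cluster; reduction under this scheme is the
#' identity on standard-residue sequences.
#'
#' @param type_id label for the scheme (default `"identity"`).
#' @return a `raac_scheme` of size 20.
#' @export
identity_scheme <- function(type_id = "identity") {
  raac_scheme(type_id, 20L, AA20, source = "identity alphabet")
}

#' Paths to bundled scheme tables
#'
#' Two tables ship with the package. `"curated"` is a small table of
#' well-known published reductions (Murphy BLOSUM50-derived alphabets,
#' hydropathy classes, the identity alphabet) used as a test fixture and a
#' quick default. `"synthetic673"` is a deterministic synthetic stand-in
#' with the registry dimensions of a full curated RAAC database (74 type
#' families, 673 schemes); its cluster contents are generated by
#' [synthetic_scheme_table()], not literature-curated, and it exists to
#' exercise registry-scale browsing and validation.
#'
#' @param which `"curated"` or `"synthetic673"`.
#' @return file path of the installed table.
#' @export
raackit_table <- function(which = c("curated", "synthetic673")) {
  which <- match.arg(which)
  fname <- switch(which,
    curated = "raac_table_curated.tsv",
    synthetic673 = "raac_table_synthetic_673.tsv"
  )
  path <- system.file("extdata", fname, package = "raackit")
  if (!nzchar(path)) stop("bundled table not found: ", fname, call. = FALSE)
  path
}

# Minimal deterministic linear congruential generator used so the synthetic
# table is bit-identical across R versions and RNG kinds.
lcg_next <- function(state) (1103515245 * state + 12345) %% 2147483648

lcg_permute <- function(x, state) {
  n <- length(x)
  for (i in n:2) {
    state <- lcg_next(state)
    j <- (state %% i) + 1
    tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
  }
  list(x = x, state = state)
}

#' Generate the synthetic registry-scale scheme table
#'
#' Deterministically constructs a scheme table with `n_types` type families
#' and 673 schemes in total (67 families carry sizes 2..10 and 7 families
#' sizes 2..11 when `n_types = 74`). Each family uses its own fixed
#' pseudo-random ordering of the 20 residues; each size-R scheme partitions
#' that ordering into R contiguous blocks of near-equal length, so every
#' scheme is a valid disjoint exhaustive partition. The table is a labelled
#' synthetic stand-in for a full curated RAAC database and carries no
#' biological meaning per cluster.
#'
#' @param n_types number of type families (default 74).
#' @return character vector of scheme-table lines (header included), ready
#'   for [parse_scheme_table()].
#' @export
synthetic_scheme_table <- function(n_types = 74L) {
  n_types <- as.integer(n_types)
  stopifnot(n_types >= 1L)
  # 67 families with 9 sizes + 7 families with 10 sizes = 673 when n_types=74
  n_extra <- max(0L, n_types - 67L)
  lines <- "type\tsize\tclusters\tsource"
  state <- 20190814  # fixed LCG seed
  for (t in seq_len(n_types)) {
    perm <- lcg_permute(AA20, state + t * 7919)
    ordering <- perm$x
    sizes <- if (t > 67L) 2:11 else 2:10
    for (R in sizes) {
      base <- 20L %/% R
      extra <- 20L %% R
      block_sizes <- rep(base, R) + c(rep(1L, extra), rep(0L, R - extra))
      ends <- cumsum(block_sizes)
      starts <- c(1L, head(ends, -1L) + 1L)
      clusters <- vapply(seq_len(R), function(i) {
        paste(ordering[starts[i]:ends[i]], collapse = "")
      }, character(1))
      lines <- c(lines, paste(
        paste0("t", t), R, paste(clusters, collapse = "-"),
        "synthetic stand-in (deterministic)",
        sep = "\t"
      ))
    }
  }
  lines
}
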