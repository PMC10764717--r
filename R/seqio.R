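#' Read protein sequences from FASTA
#'
#' Reads FASTA text into a tibble of protein sequences, one row per record.
#' Residues are uppercased, stop characters (`*`) are stripped, and any
#' character outside the 20 amino-acid letters is mapped to `X` with a
#' warning. Record ids (the first whitespace-delimited token of each header)
#' must be unique.
#'
#' @param input Path to a FASTA file, or a character vector containing FASTA
#'   text directly.
#' @return A tibble with columns `id`, `description` and `residues`.
#' @examples
#' read_fasta(">seq1 a kinase\nMKVLT\n")
#' @export
read_fasta <- function(input) {
  path <- as_input_file(input)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("Failed to parse FASTA input: ", conditionMessage(e)))
  )
  if (length(set) == 0) {
    abort("Empty FASTA input: no sequence records found.")
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("Duplicate sequence id(s): ", paste(dup, collapse = ", ")))
  }
  residues <- normalize_residues(unname(as.character(set)), ids)
  tibble(id = ids, description = desc, residues = residues)
}

# Uppercase, strip '*', map non-alphabet characters to 'X' (warning).
normalize_residues <- function(residues, ids) {
  out <- gsub("*", "", toupper(residues), fixed = TRUE)
  bad <- grepl(AA_REGEX, out)
  if (any(bad)) {
    warn(paste0("Mapped non-standard residues to 'X' in: ",
                paste(head(ids[bad], 5), collapse = ", "),
                if (sum(bad) > 5) paste0(" (and ", sum(bad) - 5, " more)")))
    out[bad] <- gsub(AA_REGEX, "X", out[bad])
  }
  empty <- !nzchar(out)
  if (any(empty)) {
    abort(paste0("Empty residue string for sequence(s): ",
                 paste(ids[empty], collapse = ", ")))
  }
  out
}

# Accept either a path or literal text; return a readable file path.
as_input_file <- function(input) {
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    return(input)
  }
  if (!any(nzchar(input))) abort("Empty input: no text supplied.")
  tmp <- tempfile(fileext = ".txt")
  writeLines(unlist(strsplit(paste(input, collapse = "\n"), "\n")), tmp)
  tmp
}

#' Write protein sequences to FASTA
#'
#' @param seqs A tibble with columns `id`, `residues` and optionally
#'   `description`, as returned by [read_fasta()].
#' @param path Output file path.
#' @param width Line width for wrapped sequence lines (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  validate_sequences(seqs)
  if (!is.numeric(width) || width < 1) abort("`width` must be a positive integer.")
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  header <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  set <- Biostrings::BStringSet(seqs$residues)
  names(set) <- header
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Validate a sequence tibble
#'
#' Checks the invariants of a protein-sequence table: unique whitespace-free
#' ids and non-empty residue strings over the amino-acid alphabet plus `X`.
#'
#' @param seqs A tibble with columns `id` and `residues`.
#' @return `seqs`, invisibly; aborts with an informative error otherwise.
#' @export
validate_sequences <- function(seqs) {
  if (!is.data.frame(seqs) || !all(c("id", "residues") %in% names(seqs))) {
    abort("`seqs` must be a data frame with columns `id` and `residues`.")
  }
  if (nrow(seqs) == 0) abort("Empty sequence table.")
  if (anyDuplicated(seqs$id)) {
    abort(paste0("Duplicate sequence id(s): ",
                 paste(unique(seqs$id[duplicated(seqs$id)]), collapse = ", ")))
  }
  if (any(grepl("\\s", seqs$id))) abort("Sequence ids must not contain whitespace.")
  if (any(!nzchar(seqs$residues))) abort("Residue strings must be non-empty.")
  bad <- grepl(AA_REGEX, seqs$residues)
  if (any(bad)) {
    abort(paste0("Invalid residue characters in: ",
                 paste(head(seqs$id[bad], 5), collapse = ", ")))
  }
  invisible(seqs)
}

#' Read a multiple alignment
#'
#' Supports aligned FASTA (`"afa"`) and a minimal single-block Stockholm
#' dialect (`"stockholm"`: plain `id sequence` lines; `#` annotation lines
#' and the `//` terminator are ignored; `.` gaps become `-`). Rows are
#' uppercased and must share one length.
#'
#' @param input Path or literal alignment text.
#' @param format `"afa"` or `"stockholm"`.
#' @return A tibble with columns `id` and `aligned` (gapped rows, all the
#'   same width).
#' @export
read_alignment <- function(input, format = c("afa", "stockholm")) {
  format <- match.arg(format)
  if (format == "afa") {
    path <- as_input_file(input)
    set <- tryCatch(
      Biostrings::readBStringSet(path),
      error = function(e) abort(paste0("Failed to parse alignment: ", conditionMessage(e)))
    )
    ids <- sub("\\s.*$", "", names(set))
    rows <- as.character(set)
  } else {
    lines <- readLines(as_input_file(input))
    lines <- lines[!grepl("^\\s*(#|//)", lines) & nzchar(trimws(lines))]
    lines <- lines[!grepl("^\\s*$", lines)]
    if (length(lines) == 0) abort("Empty Stockholm input.")
    parts <- strsplit(trimws(lines), "\\s+")
    if (any(lengths(parts) != 2)) abort("Malformed Stockholm sequence line.")
    ids0 <- vapply(parts, `[[`, "", 1)
    seqs0 <- vapply(parts, `[[`, "", 2)
    # tolerate interleaved blocks by concatenating per id, first-seen order
    ids <- unique(ids0)
    rows <- vapply(ids, function(i) paste(seqs0[ids0 == i], collapse = ""), "")
  }
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate alignment id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  rows <- chartr(".", "-", toupper(rows))
  widths <- nchar(rows)
  if (length(unique(widths)) > 1) {
    off <- widths != widths[1]
    abort(paste0("Ragged alignment rows: ", paste(ids[off], collapse = ", "),
                 " (lengths ", paste(unique(widths), collapse = "/"), ")"))
  }
  if (length(rows) < 2) abort("An alignment needs at least 2 rows.")
  ungapped <- gsub("-", "", rows, fixed = TRUE)
  bad <- grepl(AA_REGEX, ungapped)
  if (any(bad)) {
    warn(paste0("Mapped non-standard residues to 'X' in alignment rows: ",
                paste(head(ids[bad], 5), collapse = ", ")))
    rows[bad] <- vapply(rows[bad], function(r) {
      gsub(paste0("(?![-])", AA_REGEX), "X", r, perl = TRUE)
    }, "")
  }
  tibble(id = ids, aligned = unname(rows))
}

#' Remove redundant sequences
#'
#' Drops every sequence whose residue string equals, or is a substring of,
#' another sequence's residues. Within a redundant group the longest
#' sequence survives; ties are broken by the lexicographically smallest id.
#' Surviving rows keep their input order. This mirrors redundancy removal as
#' done when curating KS-domain collections before scoring.
#'
#' @param seqs A sequence tibble (see [read_fasta()]).
#' @return The dereplicated tibble.
#' @export
dereplicate <- function(seqs) {
  validate_sequences(seqs)
  n <- nrow(seqs)
  if (n <= 1) return(seqs)
  ord <- order(-nchar(seqs$residues), seqs$id)
  kept_res <- character(0)
  kept_idx <- integer(0)
  for (i in ord) {
    r <- seqs$residues[i]
    covered <- any(vapply(kept_res, function(k) {
      nchar(k) >= nchar(r) && grepl(r, k, fixed = TRUE)
    }, logical(1)))
    if (!covered) {
      kept_res <- c(kept_res, r)
      kept_idx <- c(kept_idx, i)
    }
  }
  seqs[sort(kept_idx), , drop = FALSE]
}

#' Write a score matrix as TSV
#'
#' Writes a sequences-by-HMMs bit-score table in the style of tabular
#' homology-search output: a `seq_id` column followed by one column per
#' model, scores printed with one decimal place, missing scores as `0.0`.
#'
#' @param scores A wide tibble: `seq_id` plus one numeric column per HMM.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  if (!is.data.frame(scores) || names(scores)[1] != "seq_id") {
    abort("`scores` must be a data frame whose first column is `seq_id`.")
  }
  out <- scores
  for (j in setdiff(names(out), "seq_id")) {
    v <- out[[j]]
    v[is.na(v)] <- 0
    out[[j]] <- sprintf("%.1f", v)
  }
  lines <- c(paste(names(out), collapse = "\t"),
             if (nrow(out) > 0)
               do.call(paste, c(as.list(out), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a score matrix written by [write_scores_tsv()]
#'
#' @param path TSV file path.
#' @return A wide tibble: `seq_id` plus numeric score columns.
#' @export
read_scores_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0) abort("Empty score table.")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "seq_id") abort("Score table must start with a `seq_id` column.")
  if (length(lines) == 1) {
    out <- c(list(character(0)), rep(list(numeric(0)), length(header) - 1))
    names(out) <- header
    return(as_tibble(out))
  }
  cells <- strsplit(lines[-1], "\t", fixed = TRUE)
  mat <- do.call(rbind, cells)
  out <- tibble(seq_id = mat[, 1])
  for (j in seq_along(header)[-1]) out[[header[j]]] <- as.numeric(mat[, j])
  out
}
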