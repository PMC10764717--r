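#' Read a HMMER3 ASCII profile
#'
#' Parses the `HMMER3/f` ASCII dialect (header, `LENG`, `ALPH amino`, model
#' lines of negative natural-log probabilities) into a `profile_hmm`.
#' `*` entries are read as probability 0, floored to 1e-9, and each
#' probability group renormalized. A `COMPO` line, if present, supplies the
#' background; otherwise the background is uniform. Per-node insert
#' emissions are averaged into the single shared insert vector this package
#' uses. Only the amino alphabet is supported.
#'
#' @param input Path to a `.hmm` file, or its text.
#' @return A `profile_hmm`.
#' @export
read_hmmer3_ascii <- function(input) {
  lines <- readLines(as_input_file(input))
  parse_num_line <- function(i, n_expected, skip_first = 0) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (skip_first > 0) toks <- toks[-seq_len(skip_first)]
    toks <- toks[seq_len(min(n_expected, length(toks)))]
    if (length(toks) < n_expected) {
      abort(paste0("Parse error at line ", i, ": expected ", n_expected,
                   " values, found ", length(toks), "."))
    }
    vals <- suppressWarnings(ifelse(toks == "*", Inf, as.numeric(toks)))
    if (any(is.na(vals))) {
      abort(paste0("Parse error at line ", i, ": non-numeric field."))
    }
    exp(-vals)                                  # '*' -> exp(-Inf) = 0
  }
  floor_norm <- function(p) {
    p <- pmax(p, 1e-9)
    p / sum(p)
  }

  if (!any(grepl("^HMMER3", lines[1]))) {
    abort("Parse error at line 1: not a HMMER3 ASCII profile.")
  }
  name <- "hmmer3_profile"
  leng <- NA_integer_
  header_end <- NA_integer_
  alpha_letters <- NULL
  for (i in seq_along(lines)) {
    if (grepl("^NAME\\s", lines[i])) name <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    if (grepl("^LENG\\s", lines[i])) leng <- as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]][2])
    if (grepl("^ALPH\\s", lines[i])) {
      alph <- tolower(strsplit(trimws(lines[i]), "\\s+")[[1]][2])
      if (alph != "amino") abort(paste0("Unsupported alphabet: ", alph))
    }
    if (grepl("^HMM\\s", lines[i])) {
      alpha_letters <- strsplit(trimws(lines[i]), "\\s+")[[1]][-1]
      header_end <- i
      break
    }
  }
  if (is.na(header_end)) abort("Parse error: no HMM model section found.")
  if (is.na(leng) || leng < 1) abort("Parse error: missing or invalid LENG.")
  if (length(alpha_letters) != 20 || !setequal(alpha_letters, AA_ALPHABET)) {
    abort("Unsupported alphabet: expected the 20 amino-acid letters.")
  }
  perm <- match(AA_ALPHABET, alpha_letters)

  i <- header_end + 2                           # skip the transition header line
  bg <- uniform_background()
  if (grepl("^\\s*COMPO\\s", lines[i])) {
    bg <- floor_norm(parse_num_line(i, 20, skip_first = 1)[perm])
    i <- i + 1
  }
  # node 0: insert emissions (ignored beyond averaging) + transitions
  ins_rows <- matrix(NA_real_, leng + 1, 20)
  ins_rows[1, ] <- parse_num_line(i, 20)[perm]
  tr <- matrix(NA_real_, leng + 1, 7)
  tr[1, ] <- parse_num_line(i + 1, 7)
  i <- i + 2
  me <- matrix(NA_real_, leng, 20)
  for (k in seq_len(leng)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (identical(toks[1], "//")) abort(paste0("Parse error at line ", i, ": truncated model."))
    if (suppressWarnings(as.integer(toks[1])) != k) {
      abort(paste0("Parse error at line ", i, ": expected node ", k, "."))
    }
    me[k, ] <- floor_norm(parse_num_line(i, 20, skip_first = 1)[perm])
    ins_rows[k + 1, ] <- parse_num_line(i + 1, 20)[perm]
    tr[k + 1, ] <- parse_num_line(i + 2, 7)
    i <- i + 3
  }
  ie <- floor_norm(colMeans(ins_rows))
  for (k in seq_len(leng + 1)) {
    tr[k, 1:3] <- floor_norm(tr[k, 1:3])
    tr[k, 4:5] <- floor_norm(tr[k, 4:5])
    tr[k, 6:7] <- floor_norm(tr[k, 6:7])
  }
  new_profile_hmm(name = name, match_emissions = me, insert_emissions = ie,
                  transitions = tr, background = bg)
}

PROFILE_SCHEMA <- "ksclass_profile"
PROFILE_SCHEMA_VERSION <- 1L

#' Serialize a profile HMM to JSON
#'
#' Lossless, versioned native serialization; [read_profile_json()] restores
#' the object exactly.
#'
#' @param hmm A `profile_hmm`.
#' @param path Optional file path; when given, the JSON is also written there.
#' @return The JSON text, invisibly when `path` is given.
#' @export
write_profile_json <- function(hmm, path = NULL) {
  validate_profile_hmm(hmm)
  obj <- list(
    schema = PROFILE_SCHEMA,
    version = PROFILE_SCHEMA_VERSION,
    name = hmm$name,
    m = hmm$M,
    alphabet = paste(AA_ALPHABET, collapse = ""),
    background = hmm$background,
    match_emissions = hmm$match_emissions,
    insert_emissions = hmm$insert_emissions,
    transitions = hmm$transitions
  )
  # 17 significant digits: lossless text round-trip for IEEE doubles
  txt <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' Read a profile HMM from its JSON serialization
#'
#' @param input JSON text or a file path.
#' @return A `profile_hmm`.
#' @export
read_profile_json <- function(input) {
  txt <- if (length(input) == 1 && !grepl("[{\n]", input) && file.exists(input)) {
    paste(readLines(input), collapse = "\n")
  } else {
    paste(input, collapse = "\n")
  }
  obj <- tryCatch(jsonlite::fromJSON(txt),
                  error = function(e) abort(paste0("Invalid profile JSON: ",
                                                   conditionMessage(e))))
  if (!identical(obj$schema, PROFILE_SCHEMA)) {
    abort("Schema mismatch: not a ksclass profile serialization.")
  }
  if (!identical(as.integer(obj$version), PROFILE_SCHEMA_VERSION)) {
    abort(paste0("Unsupported profile schema version: ", obj$version))
  }
  required <- c("name", "m", "background", "match_emissions",
                "insert_emissions", "transitions")
  missing <- setdiff(required, names(obj))
  if (length(missing) > 0) {
    abort(paste0("Invalid profile JSON: missing field(s) ",
                 paste(missing, collapse = ", ")))
  }
  me <- obj$match_emissions
  if (is.null(dim(me))) me <- matrix(me, nrow = obj$m, byrow = FALSE)
  new_profile_hmm(name = obj$name, match_emissions = me,
                  insert_emissions = obj$insert_emissions,
                  transitions = obj$transitions,
                  background = obj$background)
}
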