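# Corpus dialect: one UTF-8 text file per participant (filename stem = id).
# Each file is a sequence of line-initial tag markers, each followed by the
# narrative text (which may start on the tag line after the optional colon
# and continue until the next tag line). Canonical tag form on write:
# ++EMOTION(C1/C2)++ with no interior spaces.

# Grammar: "++" WS? EMOTION WS? ("(" CODE ("/" CODE)* ")")? WS? "++" ":"?
TAG_REGEX <- paste0(
  "^\\s*\\+\\+\\s*([A-Za-z]+)\\s*",
  "(?:\\(\\s*([A-Za-z]+(?:\\s*/\\s*[A-Za-z]+)*)\\s*\\))?",
  "\\s*\\+\\+(:)?(.*)$"
)

looks_like_tag <- function(line) grepl("^\\s*\\+\\+", line)

# returns NULL when the line does not match the tag grammar
match_tag_line <- function(line) {
  m <- regmatches(line, regexec(TAG_REGEX, line))[[1]]
  if (!length(m)) return(NULL)
  codes <- m[3]
  codes <- if (nzchar(codes)) {
    toupper(trimws(strsplit(codes, "/", fixed = TRUE)[[1]]))
  } else {
    character()
  }
  list(primary = toupper(m[2]), codes = codes, rest = m[5])
}

#' Construct an emotion tag
#'
#' @param primary One of `HAPPY`, `SAD`, `ANGRY`, `FEAR`, `DISGUST`, `EMPTY`.
#' @param codes Character vector of subcategory codes (must be empty iff
#'   `primary` is `EMPTY`); each code must map to `primary` under the
#'   taxonomy (`PC` may sit under `FEAR` or `HAPPY`).
#' @return An object of class `emotion_tag`.
#' @export
emotion_tag <- function(primary, codes = character()) {
  if (!is_string(primary)) abort_("tag primary must be a single string")
  primary <- toupper(primary)
  if (!primary %in% c(PRIMARY_EMOTIONS, "EMPTY"))
    abort_("unknown emotion name: %s", primary)
  codes <- toupper(as.character(codes))
  if (primary == "EMPTY" && length(codes))
    abort_("EMPTY tags cannot carry subcategory codes (got %s)",
           paste(codes, collapse = "/"))
  bad <- setdiff(codes, EMOTION_CODES)
  if (length(bad)) abort_("unknown subcategory code(s): %s",
                          paste(bad, collapse = ", "))
  if (anyDuplicated(codes))
    abort_("duplicate subcategory code(s) in tag: %s",
           paste(unique(codes[duplicated(codes)]), collapse = ", "))
  if (length(codes)) {
    ok <- codes %in% codes_for_primary(primary)
    if (!all(ok))
      abort_("code(s) %s do not belong to primary emotion %s",
             paste(codes[!ok], collapse = ", "), primary)
  }
  structure(list(primary = primary, codes = codes), class = "emotion_tag")
}

#' Parse an emotion tag line
#'
#' Parses a line of the form `++EMOTION(C1/C2)++:` (case-insensitive emotion
#' name, optional whitespace, optional subcategory list, optional trailing
#' colon) into an [emotion_tag()].
#'
#' @param line A single string holding the tag and nothing else.
#' @return An `emotion_tag`.
#' @export
#' @examples
#' parse_tag("++HAPPY (PH/PD) ++:")
#' parse_tag("++EMPTY++")
parse_tag <- function(line) {
  if (!is_string(line)) abort_("`line` must be a single string")
  m <- match_tag_line(line)
  if (is.null(m))
    abort_("malformed tag delimiter in line: %s", line)
  if (nzchar(trimws(m$rest)))
    abort_("unexpected trailing text after tag: %s", trimws(m$rest))
  emotion_tag(m$primary, m$codes)
}

#' @export
format.emotion_tag <- function(x, ...) {
  paste0("++", x$primary,
         if (length(x$codes)) paste0("(", paste(x$codes, collapse = "/"), ")"),
         "++")
}

#' @export
print.emotion_tag <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

METADATA_COLUMNS <- c("id", "group", "gender", "marital_status", "age",
                      "days_in_hospital")

GROUP_LEVELS <- c("patient", "control")

#' Construct a corpus object
#'
#' A corpus couples a participant metadata table with a narrative table. Most
#' users will obtain one from [read_corpus()] or [generate_corpus()] rather
#' than calling this directly.
#'
#' @param metadata Tibble with columns `id`, `group` (`"patient"` or
#'   `"control"`), `gender`, `marital_status`, `age`, `days_in_hospital`
#'   (`days_in_hospital` must be `NA` for controls).
#' @param narratives Tibble with columns `id`, `ordinal` (consecutive from 1
#'   within each participant), `primary`, `codes` (list column of character
#'   vectors), `text` (non-empty after whitespace stripping).
#' @return An object of class `emonarr_corpus`.
#' @export
new_corpus <- function(metadata, narratives) {
  metadata <- tibble::as_tibble(metadata)
  narratives <- tibble::as_tibble(narratives)
  miss <- setdiff(METADATA_COLUMNS, names(metadata))
  if (length(miss)) abort_("metadata is missing column(s): %s",
                           paste(miss, collapse = ", "))
  metadata <- metadata[METADATA_COLUMNS]
  if (any(is.na(metadata$id) | !nzchar(metadata$id)))
    abort_("participant ids must be non-empty")
  if (anyDuplicated(metadata$id))
    abort_("duplicate participant id(s): %s",
           paste(unique(metadata$id[duplicated(metadata$id)]), collapse = ", "))
  bad <- setdiff(unique(metadata$group), GROUP_LEVELS)
  if (length(bad)) abort_("group must be one of %s (got %s)",
                          paste(GROUP_LEVELS, collapse = "/"),
                          paste(bad, collapse = ", "))
  metadata$age <- as.numeric(metadata$age)
  metadata$days_in_hospital <- as.numeric(metadata$days_in_hospital)
  ctrl_days <- metadata$group == "control" & !is.na(metadata$days_in_hospital)
  if (any(ctrl_days))
    abort_("days_in_hospital must be absent for controls: %s",
           paste(metadata$id[ctrl_days], collapse = ", "))

  need <- c("id", "ordinal", "primary", "codes", "text")
  miss <- setdiff(need, names(narratives))
  if (length(miss)) abort_("narratives is missing column(s): %s",
                           paste(miss, collapse = ", "))
  narratives <- narratives[need]
  orphan <- setdiff(unique(narratives$id), metadata$id)
  if (length(orphan)) abort_("narratives reference unknown id(s): %s",
                             paste(orphan, collapse = ", "))
  empty_part <- setdiff(metadata$id, unique(narratives$id))
  if (length(empty_part))
    abort_("participant(s) with no narratives: %s",
           paste(empty_part, collapse = ", "))
  narratives$text <- trimws(narratives$text)
  if (any(!nzchar(narratives$text)))
    abort_("narrative text must be non-empty after stripping whitespace")
  # re-validate every tag (primary/codes consistency, EMPTY rule)
  Map(emotion_tag, narratives$primary, narratives$codes)
  narratives <- narratives[order(match(narratives$id, metadata$id),
                                 narratives$ordinal), ]
  for (pid in metadata$id) {
    o <- narratives$ordinal[narratives$id == pid]
    if (!identical(as.integer(o), seq_along(o)))
      abort_("ordinals for participant %s are not consecutive from 1", pid)
  }
  narratives$ordinal <- as.integer(narratives$ordinal)
  structure(list(metadata = metadata, narratives = narratives),
            class = "emonarr_corpus")
}

#' @export
print.emonarr_corpus <- function(x, ...) {
  n_by_group <- table(x$metadata$group)
  cat(sprintf("<emonarr_corpus> %d participants (%s), %d narratives\n",
              nrow(x$metadata),
              paste(sprintf("%s %s", names(n_by_group), n_by_group),
                    collapse = ", "),
              nrow(x$narratives)))
  tab <- table(factor(x$narratives$primary,
                      levels = c(PRIMARY_EMOTIONS, "EMPTY")))
  cat("narratives by emotion:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

read_metadata <- function(path) {
  if (!file.exists(path)) abort_("metadata file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   colClasses = "character", na.strings = "",
                   fileEncoding = "UTF-8", check.names = FALSE)
  if (!identical(names(df), METADATA_COLUMNS))
    abort_("metadata header must be exactly: %s",
           paste(METADATA_COLUMNS, collapse = " "))
  tibble::as_tibble(df)
}

parse_participant_file <- function(path, id) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  tags <- list()
  texts <- character()
  cur_text <- character()
  seen_tag <- FALSE
  flush <- function(tag_i) {
    text <- trimws(paste(cur_text, collapse = "\n"))
    if (!nzchar(text))
      abort_("participant %s: tag %d has no narrative text (two tags %s)",
             id, tag_i, "back-to-back or trailing tag")
    text
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (looks_like_tag(ln)) {
      m <- match_tag_line(ln)
      if (is.null(m))
        abort_("participant %s, line %d: malformed tag delimiter: %s",
               id, i, trimws(ln))
      tag <- tryCatch(emotion_tag(m$primary, m$codes), error = function(e)
        abort_("participant %s, line %d: %s", id, i, conditionMessage(e)))
      if (seen_tag) {
        texts[[length(tags)]] <- flush(length(tags))
      } else if (any(nzchar(trimws(cur_text)))) {
        abort_("participant %s: text before the first tag", id)
      }
      seen_tag <- TRUE
      tags[[length(tags) + 1L]] <- tag
      cur_text <- if (nzchar(trimws(m$rest))) trimws(m$rest) else character()
    } else {
      cur_text <- c(cur_text, ln)
    }
  }
  if (!seen_tag) abort_("participant %s: file contains no tags", id)
  texts[[length(tags)]] <- flush(length(tags))
  tibble::tibble(
    id = id,
    ordinal = seq_along(tags),
    primary = vapply(tags, `[[`, "", "primary"),
    codes = lapply(tags, `[[`, "codes"),
    text = texts
  )
}

#' Read a tagged-narrative corpus
#'
#' @param corpus_path Directory holding one UTF-8 `.txt` file per
#'   participant; the filename stem is the participant id.
#' @param metadata_path Tab-delimited metadata table with header
#'   `id group gender marital_status age days_in_hospital`.
#' @return An `emonarr_corpus`.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(corpus_path, metadata_path) {
  if (!dir.exists(corpus_path)) abort_("corpus directory not found: %s",
                                       corpus_path)
  metadata <- read_metadata(metadata_path)
  if (anyDuplicated(metadata$id))
    abort_("duplicate participant id(s) in metadata")
  files <- list.files(corpus_path, pattern = "\\.txt$")
  file_ids <- sub("\\.txt$", "", files)
  missing_file <- setdiff(metadata$id, file_ids)
  if (length(missing_file))
    abort_("metadata id(s) with no corpus file: %s",
           paste(missing_file, collapse = ", "))
  extra_file <- setdiff(file_ids, metadata$id)
  if (length(extra_file))
    abort_("corpus file(s) with no metadata row: %s",
           paste(extra_file, collapse = ", "))
  narr <- lapply(metadata$id, function(pid)
    parse_participant_file(file.path(corpus_path, paste0(pid, ".txt")), pid))
  new_corpus(metadata, do.call(rbind, narr))
}

#' Write a corpus in the tagged-narrative dialect
#'
#' Emits one file per participant with canonical tags
#' (`++EMOTION(C1/C2)++:` followed by the narrative text) plus a metadata
#' TSV. `read_corpus(write_corpus(x))` reproduces `x` field for field.
#'
#' @param corpus An `emonarr_corpus`.
#' @param corpus_path Output directory (created if needed).
#' @param metadata_path Output path for the metadata TSV.
#' @return Invisibly, `corpus_path`.
#' @export
write_corpus <- function(corpus, corpus_path, metadata_path) {
  stopifnot(inherits(corpus, "emonarr_corpus"))
  dir.create(corpus_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(corpus_path)) abort_("cannot create directory: %s",
                                       corpus_path)
  narr <- corpus$narratives
  for (pid in corpus$metadata$id) {
    rows <- which(narr$id == pid)
    lines <- unlist(lapply(rows, function(r) {
      tag <- emotion_tag(narr$primary[[r]], narr$codes[[r]])
      c(paste0(format(tag), ":"),
        strsplit(narr$text[[r]], "\n", fixed = TRUE)[[1]],
        "")
    }))
    con <- file(file.path(corpus_path, paste0(pid, ".txt")),
                open = "wb")
    writeLines(enc2utf8(lines), con, useBytes = TRUE)
    close(con)
  }
  md <- corpus$metadata
  md$age <- ifelse(is.na(md$age), NA,
                   format(md$age, trim = TRUE, scientific = FALSE))
  md$days_in_hospital <- ifelse(is.na(md$days_in_hospital), NA,
                                format(md$days_in_hospital, trim = TRUE,
                                       scientific = FALSE))
  write.table(as.data.frame(md), metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(corpus_path)
}
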