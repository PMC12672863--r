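#' Normalise raw transcript text to the 27-symbol alphabet
#'
#' Applies the fixed normalisation pipeline: lowercase; fold common accented
#' Latin letters to their ASCII base; delete apostrophes in place so
#' contractions collapse into a single token (`"don't"` becomes `"dont"`);
#' replace every remaining non-alphabetic character (punctuation, digits,
#' newlines, special symbols) with a space; collapse runs of spaces; strip
#' leading and trailing spaces.
#'
#' Apostrophes are the one character class deleted rather than spaced:
#' spacing them would split contractions into spurious words, while deleting
#' all punctuation outright would fuse neighbouring words (`"cat,dog"` must
#' become `"cat dog"`, not `"catdog"`) and corrupt the space-usage signal the
#' downstream model centres on.
#'
#' @param text Character vector of raw transcript text (any content,
#'   including empty strings).
#' @return Character vector of the same length containing only `a`--`z` and
#'   single interior spaces.
#' @examples
#' normalize_text("Don't!")          # "dont"
#' normalize_text("The cat,  sat.")  # "the cat sat"
#' @export
normalize_text <- function(text) {
  if (!is.character(text)) stop("`text` must be a character vector", call. = FALSE)
  x <- tolower(enc2utf8(text))
  accented <- "áàâäãåéèêëíìîïóòôöõúùûüýÿçñ"
  x <- chartr(accented, "aaaaaaeeeeiiiiooooouuuuyycn", x)
  # straight, typographic and modifier apostrophes vanish in place
  x <- gsub("['’‘ʼ`´]", "", x)
  x <- gsub("[^a-z]", " ", x)
  x <- gsub(" +", " ", x)
  trimws(x)
}

#' Encode normalised text as a character-index sequence
#'
#' Converts a single normalised string into a `char_sequence`: the observed
#' symbol stream as 1-based indices into [alphabet()], carrying transcript,
#' participant and group metadata. Input must already satisfy the
#' [normalize_text()] postcondition; any character outside the alphabet is a
#' validation error.
#'
#' @param text A single normalised string.
#' @param transcript_id,participant_id Identifier strings.
#' @param group Group label: `"case"`, `"control"` or `"unknown"`.
#' @return A `char_sequence` object.
#' @examples
#' s <- encode("a b", "t1", "p1", "case")
#' s$indices  # 1, 27, 2
#' @export
encode <- function(text, transcript_id = "t1", participant_id = transcript_id,
                   group = "unknown") {
  stopifnot(is.character(text), length(text) == 1L)
  if (nchar(text) == 0L) {
    idx <- integer(0)
  } else {
    chars <- strsplit(text, "", fixed = TRUE)[[1L]]
    idx <- match(chars, alphabet())
    if (anyNA(idx)) {
      bad <- unique(chars[is.na(idx)])
      stop("transcript ", transcript_id, ": characters outside the alphabet ",
           "(did you call normalize_text()?): ",
           paste(dQuote(bad, FALSE), collapse = ", "), call. = FALSE)
    }
  }
  char_sequence(idx, transcript_id, participant_id, group)
}

#' Construct a char_sequence from alphabet indices
#'
#' @param indices Integer vector of 1-based alphabet indices.
#' @inheritParams encode
#' @return A `char_sequence`: list with elements `indices`, `transcript_id`,
#'   `participant_id`, `group`.
#' @export
char_sequence <- function(indices, transcript_id, participant_id = transcript_id,
                          group = "unknown") {
  indices <- as.integer(indices)
  if (length(indices) && (min(indices) < 1L || max(indices) > alphabet_size()))
    stop("indices must lie in 1..27", call. = FALSE)
  sp <- space_index()
  if (length(indices)) {
    # collapse space runs, trim flanking spaces: the normal form all
    # downstream counting assumes
    keep <- c(TRUE, !(indices[-1L] == sp & indices[-length(indices)] == sp))
    indices <- indices[keep]
    while (length(indices) && indices[1L] == sp) indices <- indices[-1L]
    while (length(indices) && indices[length(indices)] == sp)
      indices <- indices[-length(indices)]
  }
  group <- match.arg(group, c("case", "control", "unknown"))
  structure(list(indices = indices,
                 transcript_id = as.character(transcript_id),
                 participant_id = as.character(participant_id),
                 group = group),
            class = "char_sequence")
}

#' @export
print.char_sequence <- function(x, ...) {
  cat("<char_sequence> ", x$transcript_id,
      " (participant ", x$participant_id, ", ", x$group, "): ",
      length(x$indices), " symbols\n", sep = "")
  if (length(x$indices)) {
    preview <- decode_indices(utils::head(x$indices, 60L))
    cat("  \"", preview, if (length(x$indices) > 60L) "..." else "", "\"\n",
        sep = "")
  }
  invisible(x)
}

#' @export
length.char_sequence <- function(x) length(x$indices)

#' Render a char_sequence back to text
#'
#' @param x A `char_sequence`.
#' @return A single string over the 27-symbol alphabet.
#' @export
decode <- function(x) {
  stopifnot(inherits(x, "char_sequence"))
  decode_indices(x$indices)
}

decode_indices <- function(indices) {
  paste(alphabet()[indices], collapse = "")
}

#' Read a transcript corpus from a manifest or directory
#'
#' Two layouts are supported. A manifest CSV with header
#' `path,label,participant_id` (paths relative to the manifest's directory or
#' absolute), or a directory containing `.txt` / `.cha` files (label
#' `"unknown"`, participant id equal to the file stem). For `.cha` files only
#' the participant speech tier is used (see [read_cha()]).
#'
#' Missing files are skipped with a warning naming each path; an empty corpus
#' (no readable transcripts) is an error.
#'
#' @param path Path to a manifest CSV or to a directory.
#' @param participant_tier Tier marker identifying the participant speaker in
#'   CHAT files (default `"PAR"`).
#' @return List of raw transcript records, each a list with `text`,
#'   `transcript_id`, `participant_id`, `group`.
#' @export
read_transcripts <- function(path, participant_tier = "PAR") {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(txt|cha)$", full.names = TRUE))
    if (!length(files))
      stop("empty corpus: no .txt or .cha files in ", path, call. = FALSE)
    records <- data.frame(path = files,
                          label = "unknown",
                          participant_id = sub("\\.[^.]+$", "", basename(files)),
                          stringsAsFactors = FALSE)
  } else if (file.exists(path)) {
    records <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("path", "label", "participant_id")
    if (!all(need %in% names(records)))
      stop("manifest must have columns path,label,participant_id", call. = FALSE)
    rel <- !grepl("^(/|[A-Za-z]:)", records$path)
    records$path[rel] <- file.path(dirname(path), records$path[rel])
  } else {
    stop("no such file or directory: ", path, call. = FALSE)
  }
  out <- vector("list", nrow(records))
  skipped <- character(0)
  for (i in seq_len(nrow(records))) {
    f <- records$path[i]
    if (!file.exists(f)) {
      skipped <- c(skipped, f)
      next
    }
    txt <- if (grepl("\\.cha$", f)) {
      read_cha(f, participant_tier = participant_tier)
    } else {
      paste(readLines(f, warn = FALSE, encoding = "UTF-8"), collapse = " ")
    }
    out[[i]] <- list(text = txt,
                     transcript_id = sub("\\.[^.]+$", "", basename(f)),
                     participant_id = as.character(records$participant_id[i]),
                     group = as.character(records$label[i]))
  }
  if (length(skipped))
    warning("skipped ", length(skipped), " missing file(s): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) stop("empty corpus: no readable transcripts", call. = FALSE)
  out
}

#' Extract the participant speech tier from a minimal CHAT file
#'
#' Reads a `.cha` transcript in a minimal dialect of the CHAT format: lines
#' beginning `*<tier>:` belong to speaker `<tier>`; a line starting with a tab
#' continues the previous tier. Only the participant tier is kept.
#' `&`-prefixed annotation codes, `[...]` and `(...)` markup, and the ``
#' time-alignment bullets are stripped before the text is returned;
#' full CHAT/CLAN parsing is out of scope.
#'
#' @param path Path to a `.cha` file.
#' @param participant_tier Tier marker of the participant (default `"PAR"`).
#' @return A single string: the concatenated participant utterances.
#' @export
read_cha <- function(path, participant_tier = "PAR") {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- character(0)
  in_tier <- FALSE
  tier_re <- paste0("^\\*", participant_tier, ":")
  for (ln in lines) {
    if (grepl(tier_re, ln)) {
      keep <- c(keep, sub(tier_re, "", ln))
      in_tier <- TRUE
    } else if (grepl("^\t", ln) && in_tier) {
      keep <- c(keep, ln)
    } else {
      in_tier <- FALSE
    }
  }
  txt <- paste(keep, collapse = " ")
  txt <- gsub("\\x15[^\\x15]*\\x15", " ", txt)  # time-alignment bullets
  txt <- gsub("\\[[^]]*\\]", " ", txt)              # [...] coding
  txt <- gsub("\\([^)]*\\)", " ", txt)              # (...) markup
  txt <- gsub("&[^ \t]*", " ", txt)                 # &-prefixed codes
  trimws(gsub("[ \t]+", " ", txt))
}

#' Build a corpus of char_sequences from raw transcript records
#'
#' Normalises and encodes each record; transcripts that are empty after
#' normalisation are excluded with a warning (they admit no transition
#' counts).
#'
#' @param records List of raw transcript records as returned by
#'   [read_transcripts()].
#' @return List of `char_sequence` objects.
#' @export
encode_corpus <- function(records) {
  out <- lapply(records, function(r) {
    txt <- normalize_text(r$text)
    if (!nchar(txt)) return(NULL)
    encode(txt, r$transcript_id, r$participant_id, r$group)
  })
  empty <- vapply(out, is.null, logical(1))
  if (any(empty)) {
    ids <- vapply(records[empty], `[[`, "", "transcript_id")
    warning("excluded ", sum(empty), " transcript(s) empty after ",
            "normalisation: ", paste(ids, collapse = ", "), call. = FALSE)
  }
  out[!empty]
}
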