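# Knowledge bases: portable, version-control friendly compilations of MMs.
#
# Layout: a directory containing one YAML document per MM (named by the
# MM's content-hash id) plus manifest.yaml carrying name, description,
# task/domain tags, a format version and a sha256 per MM file. Field order
# in every file is fixed and no timestamps are written, so re-exporting
# identical MMs yields byte-identical files that diff and merge cleanly
# under external version control.

KB_FORMAT_VERSION <- "1.0"

text_sha256 <- function(text) {
  digest::digest(text, algo = "sha256", serialize = FALSE)
}

# Byte-exact write: the manifest hash covers the file contents verbatim.
write_text_file <- function(text, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(text)), con)
  invisible(path)
}

#' Export MMs as a knowledge base
#'
#' @param mms List of `dq_mm`; all must validate.
#' @param destination Directory to create/write.
#' @param name Knowledge-base name.
#' @param description Free-text description.
#' @param kb_tags Task/domain tags of the compilation.
#' @return The destination directory, invisibly.
#' @export
export_kb <- function(mms, destination, name = basename(destination),
                      description = "", kb_tags = character(0)) {
  reports <- lapply(mms, validate_mm)
  bad <- which(lengths(reports) > 0L)
  if (length(bad) > 0L) {
    msgs <- vapply(bad, function(i) {
      sprintf("%s: %s", mms[[i]]$id,
              paste(vapply(reports[[i]], `[[`, character(1L), "code"),
                    collapse = ","))
    }, character(1L))
    dq_error("VALIDATION", paste("invalid MM(s):",
                                 paste(msgs, collapse = "; ")))
  }
  dir.create(destination, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(mms, function(mm) {
    text <- enc2utf8(render_mm_yaml(mm))
    fname <- paste0(mm$id, ".yaml")
    write_text_file(text, file.path(destination, fname))
    list(file = fname, id = mm$id, sha256 = text_sha256(text))
  })
  manifest <- list(
    format_version = KB_FORMAT_VERSION,
    name = name,
    description = description,
    tags = as.list(kb_tags),
    mms = entries)
  write_text_file(yaml::as.yaml(manifest),
                  file.path(destination, "manifest.yaml"))
  invisible(destination)
}

read_file_utf8 <- function(path) {
  raw <- readChar(path, file.info(path)$size, useBytes = TRUE)
  Encoding(raw) <- "UTF-8"
  raw
}

#' Import a knowledge base
#'
#' Verifies the manifest's format version and per-file content hashes
#' before parsing; a tampered file raises an integrity error.
#'
#' @param source Knowledge-base directory.
#' @return List of `dq_mm`.
#' @export
import_kb <- function(source) {
  manifest_path <- file.path(source, "manifest.yaml")
  dq_assert(file.exists(manifest_path), "FORMAT",
            sprintf("'%s' has no manifest.yaml", source))
  manifest <- yaml::read_yaml(manifest_path)
  if (!identical(manifest$format_version, KB_FORMAT_VERSION)) {
    dq_error("VERSION", sprintf(
      "unsupported knowledge-base format version '%s' (expected %s)",
      manifest$format_version %||% "<none>", KB_FORMAT_VERSION))
  }
  lapply(manifest$mms, function(entry) {
    path <- file.path(source, entry$file)
    dq_assert(file.exists(path), "INTEGRITY",
              sprintf("MM file '%s' listed in manifest is absent",
                      entry$file))
    text <- read_file_utf8(path)
    if (!identical(text_sha256(text), entry$sha256)) {
      dq_error("INTEGRITY", sprintf(
        "MM file '%s' does not match its manifest hash", entry$file))
    }
    mm_from_document(yaml::yaml.load(text))
  })
}

#' Bind a knowledge base to a dataset
#'
#' An MM is applicable iff every one of its dataset-binding paths matches
#' at least one node in at least one row; filter-only MMs are always
#' applicable. Unmatched MMs are reported with their missing paths, never
#' raised as errors — cross-dataset reuse is the point of knowledge bases.
#'
#' @param mms List of `dq_mm`.
#' @param dataset A `dq_dataset`.
#' @return List with `applicable` (the usable MMs) and `unmatched`
#'   (`data.frame` mm_id, missing_paths).
#' @export
bind_kb_to_dataset <- function(mms, dataset) {
  path_resolves <- function(parsed) {
    for (row in dataset$rows) {
      probe <- parsed
      probe$count_mode <- NULL
      if (length(match_nodes(row, probe)) > 0L) return(TRUE)
    }
    FALSE
  }
  applicable <- list()
  unmatched <- list()
  for (mm in mms) {
    if (mm_binding_kind(mm) != "dataset") {
      applicable[[length(applicable) + 1L]] <- mm
      next
    }
    missing <- character(0)
    for (dp in mm$domain_paths) {
      parsed <- dp$parsed
      # cardinality-style paths address a parent container; probing the
      # container (not its children) decides applicability
      if (!path_resolves(parsed)) missing <- c(missing, dp$path)
    }
    if (length(missing) == 0L) {
      applicable[[length(applicable) + 1L]] <- mm
    } else {
      unmatched[[length(unmatched) + 1L]] <- data.frame(
        mm_id = mm$id, missing_paths = paste(missing, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  list(
    applicable = applicable,
    unmatched = if (length(unmatched) > 0L) do.call(rbind, unmatched) else
      data.frame(mm_id = character(0), missing_paths = character(0),
                 stringsAsFactors = FALSE))
}
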