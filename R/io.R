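readTable <- function(path) {
  stopIfNot(file.exists(path), paste0("file not found: ", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(read.delim(path, sep = sep, stringsAsFactors = FALSE,
                            check.names = FALSE),
                 error = function(e) stop("cannot read table ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) stop("empty input table: ", path, call. = FALSE)
  df
}

#' Read a labeled pair table
#'
#' Reads CCI/PPI/DTA records from TSV (or CSV, by extension). Two layouts are
#' accepted, mirroring interaction-corpus conventions:
#' \describe{
#'   \item{entity-referenced}{columns `left`, `right`, `label` (plus optional
#'     `channel` for CCI); ids resolve against `chemicals` / `proteins`
#'     stores supplied as named vectors.}
#'   \item{inline}{structures in the table itself: `left_smiles`,
#'     `right_smiles`, `label` (CCI); `left_sequence`, `right_sequence`,
#'     `label` (PPI); `smiles`, `sequence`, `affinity` (DTA). Entity ids are
#'     derived by de-duplicating the structures.}
#' }
#' Malformed rows (missing fields, non-numeric or out-of-domain labels,
#' unparsable SMILES when `validate = TRUE`) are rejected with their line
#' numbers in a warning; the remainder loads, and counts are reported.
#'
#' @param path table path.
#' @param task "cci", "ppi" or "dta".
#' @param chemicals,proteins named character stores for the
#'   entity-referenced layout.
#' @param validate re-parse SMILES and check sequences (default TRUE).
#' @return A [PairDataset-class].
#' @export
readPairTable <- function(path, task = c("cci", "ppi", "dta"),
                          chemicals = NULL, proteins = NULL,
                          validate = TRUE) {
  task <- match.arg(task)
  df <- readTable(path)
  lines <- seq_len(nrow(df)) + 1L # header is line 1

  inlineCols <- switch(task,
    cci = c("left_smiles", "right_smiles", "label"),
    ppi = c("left_sequence", "right_sequence", "label"),
    dta = c("smiles", "sequence", "affinity"))
  refCols <- c("left", "right", "label")

  if (all(inlineCols %in% names(df))) {
    lefts <- as.character(df[[inlineCols[1]]])
    rights <- as.character(df[[inlineCols[2]]])
    label <- suppressWarnings(as.numeric(df[[inlineCols[3]]]))
    if (task == "dta") {
      uc <- unique(lefts); up <- unique(rights)
      chemicals <- setNames(uc, sprintf("CHEM%04d", seq_along(uc)))
      proteins <- setNames(up, sprintf("PROT%04d", seq_along(up)))
      left <- names(chemicals)[match(lefts, chemicals)]
      right <- names(proteins)[match(rights, proteins)]
    } else {
      us <- unique(c(lefts, rights))
      store <- setNames(us, sprintf("ENT%04d", seq_along(us)))
      if (task == "cci") chemicals <- store else proteins <- store
      left <- names(store)[match(lefts, store)]
      right <- names(store)[match(rights, store)]
    }
  } else if (all(refCols %in% names(df))) {
    left <- as.character(df$left)
    right <- as.character(df$right)
    label <- suppressWarnings(as.numeric(df$label))
    leftStore <- if (task == "ppi") proteins else chemicals
    rightStore <- if (task == "cci") chemicals else proteins
    stopIfNot(!is.null(leftStore) && !is.null(rightStore),
              "entity-referenced table needs chemicals/proteins stores")
    unresolved <- setdiff(c(left[!left %in% names(leftStore)],
                            right[!right %in% names(rightStore)]), character())
    if (length(unresolved))
      stop("unresolvable entity ids in ", path, ": ",
           paste(head(unique(unresolved), 10L), collapse = ", "),
           call. = FALSE)
  } else {
    stop(sprintf("schema error in %s: need columns %s or %s", path,
                 paste(inlineCols, collapse = "/"),
                 paste(refCols, collapse = "/")), call. = FALSE)
  }

  bad <- !is.finite(label) | is.na(left) | is.na(right)
  if (task != "dta") bad <- bad | !(label %in% c(0, 1, NA))
  if (validate && task != "ppi") {
    smilesStore <- chemicals
    parsed <- suppressWarnings(parseSmilesSet(smilesStore))
    if (length(parsed$failed)) {
      badIds <- parsed$failed
      bad <- bad | left %in% badIds | (task == "cci" & right %in% badIds)
      chemicals <- chemicals[!names(chemicals) %in% badIds]
    }
  }
  if (any(bad)) {
    warning(sprintf("%s: rejected %d malformed row(s) at line(s) %s",
                    path, sum(bad),
                    paste(head(lines[bad], 10L), collapse = ", ")))
    left <- left[!bad]; right <- right[!bad]; label <- label[!bad]
    if (!is.null(df$channel)) df <- df[!bad, , drop = FALSE]
  }
  stopIfNot(length(left) > 0L, paste0("no valid records in ", path))
  pairs <- data.frame(left = left, right = right, label = label,
                      stringsAsFactors = FALSE)
  if (task == "cci" && !is.null(df$channel)) pairs$channel <- df$channel
  message(sprintf("read %d %s pairs from %s", nrow(pairs), task, path))
  new("PairDataset", task = task, pairs = pairs,
      chemicals = chemicals %||% character(),
      proteins = proteins %||% character())
}

#' Read protein sequences from FASTA
#'
#' Headers are parsed to ids as the first whitespace-delimited token;
#' sequences are upper-cased. Duplicated ids are an error (they would make
#' pair records ambiguous); non-standard residues are left in place and map
#' to the unknown token at encoding time.
#'
#' @param path FASTA file.
#' @return Named character vector id -> sequence.
#' @export
readProteinFasta <- function(path) {
  stopIfNot(file.exists(path), paste0("file not found: ", path))
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA ids: ", paste(head(dup, 10L), collapse = ", "),
         call. = FALSE)
  seqs <- toupper(as.character(ss))
  nonstd <- grepl(sprintf("[^%s]", paste(aminoAcidVocab(), collapse = "")), seqs)
  if (any(nonstd))
    warning(sprintf("%d sequence(s) contain non-standard residues; they map to the unknown token when encoded",
                    sum(nonstd)))
  setNames(seqs, ids)
}

#' Write pipeline artifacts
#'
#' `writePairTable` writes a dataset's records as TSV (entity-referenced
#' layout). `writeWorld` materializes a synthetic world as the exact on-disk
#' formats the real pipeline reads: `chemicals.tsv` (id, smiles),
#' `proteins.fasta`, and optional pair tables. `writeMetricsReport` /
#' `readMetricsReport` round-trip the tidy metrics TSV (run, split, metric,
#' value).
#'
#' @param dataset a [PairDataset-class].
#' @param path,dir output locations.
#' @return The written path(s), invisibly.
#' @export
writePairTable <- function(dataset, path) {
  write.table(dataset@pairs, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writePairTable
#' @param world a [SyntheticWorld-class].
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chemPath <- file.path(dir, "chemicals.tsv")
  write.table(world@chemicals, chemPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  fastaPath <- file.path(dir, "proteins.fasta")
  writeLines(paste0(">", world@proteins$id, "\n", world@proteins$sequence),
             fastaPath)
  invisible(c(chemPath, fastaPath))
}

#' @rdname writePairTable
#' @export
readChemicalTable <- function(path) {
  df <- readTable(path)
  stopIfNot(all(c("id", "smiles") %in% names(df)),
            paste0("chemical table needs columns id, smiles: ", path))
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup))
    stop("duplicate chemical ids: ", paste(head(dup, 10L), collapse = ", "),
         call. = FALSE)
  setNames(as.character(df$smiles), df$id)
}

#' @rdname writePairTable
#' @param metrics tidy metrics data.frame.
#' @export
writeMetricsReport <- function(metrics, path) {
  write.table(metrics, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePairTable
#' @export
readMetricsReport <- function(path) {
  readTable(path)
}

#' Read a run configuration file
#'
#' YAML mapping of option names to values, merged under command-line flags
#' by the CLI; see [runCli()]. Unknown keys are an error so that typos never
#' silently fall back to defaults.
#'
#' @param path YAML file.
#' @param known character vector of permitted keys.
#' @return Named list.
#' @export
readRunConfig <- function(path, known = NULL) {
  stopIfNot(file.exists(path), paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  stopIfNot(is.list(cfg), "config must be a YAML mapping")
  if (!is.null(known)) {
    bad <- setdiff(names(cfg), known)
    if (length(bad))
      stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg
}
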