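#' Read protein sequences from a FASTA file
#'
#' Parses via [Biostrings::readAAStringSet()] and validates every sequence
#' against the 20-letter amino-acid alphabet (plus `X`). Entry order is
#' preserved, whitespace is stripped and letters are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return List of `protein_record` objects (fields `id`, `sequence`, `L`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  records <- vector("list", length(set))
  nm <- names(set)
  for (i in seq_along(set)) {
    id <- sub("\\s.*$", "", nm[i])
    seq <- toupper(gsub("\\s", "", as.character(set[[i]])))
    if (!nzchar(id)) stop("FASTA record ", i, " has an empty header")
    if (!nzchar(seq)) stop("FASTA record '", id, "' has an empty sequence")
    bad <- setdiff(unique(strsplit(seq, "")[[1]]), c(AA_LETTERS, "X"))
    if (length(bad) > 0L)
      stop("FASTA record '", id, "' contains letters outside the 20+X ",
           "alphabet: ", paste(bad, collapse = ", "))
    records[[i]] <- protein_record(id, seq)
  }
  records
}

#' Construct a protein record
#' @param id Identifier string.
#' @param sequence Amino-acid sequence over the 20-letter alphabet plus `X`.
#' @export
protein_record <- function(id, sequence) {
  stopifnot(is.character(id), nzchar(id), is.character(sequence),
            nzchar(sequence))
  sequence <- toupper(sequence)
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c(AA_LETTERS, "X"))
  if (length(bad) > 0L)
    stop("sequence contains disallowed letters: ", paste(bad, collapse = ", "))
  structure(list(id = id, sequence = sequence, L = nchar(sequence)),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (L = %d)\n", x$id, x$L))
  invisible(x)
}

#' Write protein records to FASTA
#' @param records List of `protein_record`.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "protein_record")) records <- list(records)
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# three-letter -> one-letter residue code map used when reading structures
.aa321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            MSE = "M", SEC = "C", UNK = "X")

#' Read a C-alpha trace from a PDB or mmCIF file
#'
#' Parses the file with bio3d, keeps the first model only, selects one chain
#' and extracts one record per residue: its C-alpha coordinates, one-letter
#' residue type and the B-factor column as a per-residue confidence (pLDDT
#' for predicted structures). Residues lacking a C-alpha atom are dropped
#' with a warning; residues are renumbered 1..L in chain order regardless of
#' author numbering, and variant positions throughout the package refer to
#' this internal numbering.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param chain Chain identifier; default takes the first chain in the file.
#' @return Object of class `structure_model`: list with `id`, `chain` and a
#'   data.frame `residues` (columns `residue_index`, `residue_type`, `x`,
#'   `y`, `z`, `confidence`).
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  } else {
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, multi = FALSE))
  }
  atoms <- pdb$atom
  chains <- unique(atoms$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains)
    stop("chain '", chain, "' not present in ", path,
         " (available: ", paste(chains, collapse = ", "), ")")
  atoms <- atoms[atoms$chain == chain & atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM records for chain '", chain, "'")
  # residue identity in file order
  res_key <- paste(atoms$resno, atoms$insert)
  keys <- unique(res_key)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$resno, ca$insert)), , drop = FALSE]
  ca_keys <- paste(ca$resno, ca$insert)
  missing_ca <- setdiff(keys, ca_keys)
  if (length(missing_ca) > 0L)
    warning(length(missing_ca), " residue(s) without a C-alpha atom were ",
            "dropped from chain '", chain, "'")
  # keep file order of residues that do have a CA
  ca <- ca[match(intersect(keys, ca_keys), ca_keys), , drop = FALSE]
  if (nrow(ca) == 0L) stop("chain '", chain, "' has no C-alpha atoms")
  rt <- .aa321[ca$resid]
  rt[is.na(rt)] <- "X"
  res <- data.frame(residue_index = seq_len(nrow(ca)),
                    residue_type = unname(rt),
                    x = ca$x, y = ca$y, z = ca$z,
                    confidence = ca$b,
                    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(res[, c("x", "y", "z")]))))
    stop("non-finite C-alpha coordinates in ", path)
  structure(list(id = tools::file_path_sans_ext(basename(path)),
                 chain = chain, residues = res),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s chain %s: %d residues, mean conf %.1f\n",
              x$id, x$chain, nrow(x$residues), mean(x$residues$confidence)))
  invisible(x)
}

#' Sequence of a structure model
#' @param s A `structure_model`.
#' @export
structure_sequence <- function(s) paste(s$residues$residue_type, collapse = "")

#' Training-set admission filter
#'
#' A structure is admitted to the self-supervised training set when its chain
#' is at least `min_len` residues long and its mean per-residue confidence
#' (pLDDT) is at least `min_mean_confidence`. Both comparisons keep the
#' boundary: exactly 64 residues or a mean pLDDT of exactly 70 passes, since
#' the removal rules are strict ("shorter than" / "lower than").
#'
#' @param s A `structure_model`.
#' @param min_len Minimum length in residues (default 64).
#' @param min_mean_confidence Minimum mean confidence (default 70).
#' @return Logical scalar.
#' @export
admit_for_training <- function(s, min_len = 64, min_mean_confidence = 70) {
  stopifnot(inherits(s, "structure_model"))
  nrow(s$residues) >= min_len &&
    mean(s$residues$confidence) >= min_mean_confidence
}

#' Write a score table as TSV
#'
#' Tab-separated with a header row; run metadata (config hash, seed, ...) is
#' written as leading `#` comment lines. Rows are ordered by rank, ties by
#' variant string, so output is deterministic.
#'
#' @param rows A `score_table` (data.frame with at least `variant`, `score`,
#'   `rank`) or compatible data.frame.
#' @param path Output path.
#' @param metadata Named list written as `# key: value` comment lines.
#' @export
write_score_table <- function(rows, path, metadata = attr(rows, "metadata")) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) > 0L) {
    ord <- order(rows$rank, rows$variant)
    rows <- rows[ord, , drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata))
    for (k in names(metadata))
      writeLines(sprintf("# %s: %s", k, as.character(metadata[[k]])), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#' @param path Path to the TSV.
#' @export
read_score_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  meta <- list()
  for (m in meta_lines) {
    kv <- sub("^#\\s*", "", m)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  attr(tab, "metadata") <- meta
  class(tab) <- c("score_table", class(tab))
  tab
}
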