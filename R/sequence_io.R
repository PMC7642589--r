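# Reading, validating and writing protein sequences and label assignments.

#' Construct a labeled protein dataset
#'
#' A light container holding sequence identifiers, residue strings and an
#' optional binary label per sequence (1 = thermophilic/positive,
#' 0 = non-thermophilic/negative, NA = unlabeled).
#'
#' @param id Character vector of unique identifiers.
#' @param seq Character vector of residue strings (same length as `id`).
#' @param label Integer vector of 0/1/NA labels, recycled NA if omitted.
#' @return An object of class `aa_dataset`: a list with elements `id`,
#'   `seq`, `label`.
#' @export
aa_dataset <- function(id, seq, label = rep(NA_integer_, length(id))) {
  stopifnot(length(id) == length(seq), length(label) == length(id))
  if (anyDuplicated(id)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  label <- as.integer(label)
  if (any(!is.na(label) & !(label %in% c(0L, 1L)))) {
    stop("labels must be 0, 1 or NA")
  }
  structure(list(id = as.character(id), seq = toupper(as.character(seq)),
                 label = label),
            class = "aa_dataset")
}

#' @export
length.aa_dataset <- function(x) length(x$id)

#' @export
print.aa_dataset <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<aa_dataset> %d sequences", n))
  if (any(!is.na(x$label))) {
    cat(sprintf(" (%d positive, %d negative)",
                sum(x$label == 1L, na.rm = TRUE),
                sum(x$label == 0L, na.rm = TRUE)))
  }
  cat("\n")
  if (n > 0) {
    show <- seq_len(min(n, 5))
    for (i in show) {
      cat(sprintf("  %s [%d aa]%s\n", x$id[i], nchar(x$seq[i]),
                  if (is.na(x$label[i])) "" else paste0(" label=", x$label[i])))
    }
    if (n > 5) cat(sprintf("  ... and %d more\n", n - 5))
  }
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into an `aa_dataset`. Sequence lines belonging to one
#' header are concatenated, record order is preserved and residues are
#' uppercased. The identifier is the first whitespace-delimited token of the
#' header. No alphabet validation is performed here; see
#' [validate_sequence()].
#'
#' @param path Path to an existing FASTA file.
#' @return An `aa_dataset` with `label = NA`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("failed to parse FASTA '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  empty <- which(nchar(seqs) == 0)
  if (length(empty) > 0) {
    stop("record(s) with empty sequence in '", path, "': ",
         paste(ids[empty], collapse = ", "))
  }
  aa_dataset(ids, seqs)
}

#' Write protein sequences to a FASTA file
#'
#' Writes an `aa_dataset` (or parallel id/seq vectors) as FASTA with
#' 60-column line wrapping.
#'
#' @param x An `aa_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "aa_dataset"))
  set <- Biostrings::BStringSet(x$seq)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Validate a protein sequence against the canonical alphabet
#'
#' Accepts exactly the non-empty sequences drawn from the 20-letter canonical
#' amino-acid alphabet after uppercasing. Ambiguity codes (B, J, O, U, X, Z),
#' stops (`*`) and gap characters are rejected; the verdict names the first
#' offending character and its 1-based position. Selenocysteine (U) records
#' are rejected rather than recoded.
#'
#' @param seq A single residue string.
#' @return A list with elements `ok` (logical) and `reason` (`NA` when
#'   accepted, otherwise a message naming the offending residue).
#' @export
validate_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  s <- toupper(seq)
  if (nchar(s) == 0) {
    return(list(ok = FALSE, reason = "empty sequence"))
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% aa_alphabet()))
  if (length(bad) > 0) {
    i <- bad[1]
    return(list(ok = FALSE,
                reason = sprintf("non-canonical residue '%s' at position %d",
                                 chars[i], i)))
  }
  list(ok = TRUE, reason = NA_character_)
}

# Vectorized validity over a dataset; returns logical vector.
.valid_mask <- function(ds) {
  grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", ds$seq)
}

#' Load a labeled two-class dataset from paired FASTA files
#'
#' Reads positives (label 1) and negatives (label 0) from separate FASTA
#' files, screens out sequences containing non-canonical residues, and
#' checks the class structure required for training.
#'
#' @param pos_path FASTA of positive-class (thermophilic) sequences.
#' @param neg_path FASTA of negative-class sequences.
#' @param strict If `TRUE`, any invalid sequence is a hard error; otherwise
#'   invalid sequences are dropped with a warning giving the count.
#' @return An `aa_dataset` with labels.
#' @export
load_labeled <- function(pos_path, neg_path, strict = FALSE) {
  pos <- read_fasta(pos_path)
  neg <- read_fasta(neg_path)
  dup <- intersect(pos$id, neg$id)
  if (length(dup) > 0) {
    stop("identifier(s) present in both classes: ",
         paste(dup, collapse = ", "))
  }
  ds <- aa_dataset(c(pos$id, neg$id), c(pos$seq, neg$seq),
                   c(rep(1L, length(pos)), rep(0L, length(neg))))
  ok <- .valid_mask(ds)
  if (any(!ok)) {
    if (strict) {
      stop(sum(!ok), " sequence(s) failed alphabet screening: ",
           paste(utils::head(ds$id[!ok], 5), collapse = ", "))
    }
    warning("dropped ", sum(!ok),
            " sequence(s) containing non-canonical residues")
    ds <- subset_dataset(ds, which(ok))
  }
  if (sum(ds$label == 1L) == 0 || sum(ds$label == 0L) == 0) {
    stop("one class is empty after validation")
  }
  ds
}

#' Subset a dataset by index
#'
#' @param ds An `aa_dataset`.
#' @param idx Integer indices to keep.
#' @return The subsetted `aa_dataset`.
#' @export
subset_dataset <- function(ds, idx) {
  aa_dataset(ds$id[idx], ds$seq[idx], ds$label[idx])
}

#' Read labels from a two-column TSV
#'
#' Header-less, tab-separated `id<TAB>label` with labels 0/1. Labels are
#' attached to a dataset by id; an id in the table but not the dataset is an
#' error, as is a label conflicting with one already present.
#'
#' @param ds An `aa_dataset`.
#' @param path Path to the label TSV.
#' @return The dataset with labels filled in.
#' @export
attach_labels <- function(ds, path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "integer"),
                           col.names = c("id", "label"))
  if (anyDuplicated(tab$id)) stop("duplicate ids in label table")
  missing <- setdiff(tab$id, ds$id)
  if (length(missing) > 0) {
    stop("label table refers to unknown id(s): ",
         paste(missing, collapse = ", "))
  }
  m <- match(ds$id, tab$id)
  new_lab <- tab$label[m]
  clash <- !is.na(ds$label) & !is.na(new_lab) & ds$label != new_lab
  if (any(clash)) {
    stop("conflicting labels for id(s): ",
         paste(ds$id[clash], collapse = ", "))
  }
  ds$label <- ifelse(is.na(new_lab), ds$label, new_lab)
  ds
}
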