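# The ten descriptor encodings. Every encoder maps one validated protein
# sequence to a named numeric vector with a fixed, documented feature order;
# k-mer windows overlap, so a length-n sequence has n-1 dipeptides and n-2
# tripeptides, which fixes the denominators.

# Residue string -> integer indices into aa_alphabet(); errors on
# non-canonical characters so encoders never see invalid input.
.seq_index <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, aa_alphabet())
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("non-canonical residue '%s' at position %d", chars[bad], bad))
  }
  idx
}

# Residue string -> integer group indices under a named partition list.
.group_index <- function(seq, partition) {
  lut <- integer(20)
  for (g in seq_along(partition)) {
    lut[match(partition[[g]], aa_alphabet())] <- g
  }
  lut[.seq_index(seq)]
}

.kmer_names <- function(tokens, k, sep = "") {
  m <- length(tokens)
  grids <- lapply(seq_len(k), function(j) {
    rep(rep(tokens, each = m ^ (k - j)), times = m ^ (j - 1))
  })
  do.call(paste, c(grids, sep = sep))
}

# Count overlapping k-mers of an index vector over an m-letter alphabet;
# returns counts in first-position-major (lexicographic) order.
.kmer_counts <- function(idx, k, m) {
  n <- length(idx)
  code <- idx[1:(n - k + 1)] - 1L
  if (k > 1) {
    for (j in 2:k) code <- code * m + (idx[j:(n - k + j)] - 1L)
  }
  tabulate(code + 1L, nbins = m ^ k)
}

.check_len <- function(seq, min_len, encoder) {
  if (nchar(seq) < min_len) {
    stop(sprintf("%s requires sequence length >= %d (got %d)",
                 encoder, min_len, nchar(seq)))
  }
}

#' Amino acid composition (AAC)
#'
#' Frequency of each of the 20 canonical residues, `f(i) = n(i)/n`. Values
#' sum to 1; order is the canonical alphabet.
#'
#' @param seq A residue string over the canonical alphabet.
#' @return Named numeric vector of length 20.
#' @export
encode_aac <- function(seq) {
  .check_len(seq, 1, "AAC")
  idx <- .seq_index(seq)
  stats::setNames(tabulate(idx, 20) / length(idx), aa_alphabet())
}

#' Dipeptide composition (DPC)
#'
#' Frequency of each of the 400 ordered residue pairs over the n-1
#' overlapping dipeptide windows, `f(x,y) = n_xy/(n-1)`. Feature names are
#' the two-letter pairs in lexicographic order ("AA", "AC", ...).
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 400.
#' @export
encode_dpc <- function(seq) {
  .check_len(seq, 2, "DPC")
  idx <- .seq_index(seq)
  stats::setNames(.kmer_counts(idx, 2, 20) / (length(idx) - 1),
                  .kmer_names(aa_alphabet(), 2))
}

#' Tripeptide composition (TPC)
#'
#' Frequency of each of the 8,000 ordered residue triples over the n-2
#' overlapping windows, `f(x,y,z) = n_xyz/(n-2)`.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 8000.
#' @export
encode_tpc <- function(seq) {
  .check_len(seq, 3, "TPC")
  idx <- .seq_index(seq)
  stats::setNames(.kmer_counts(idx, 3, 20) / (length(idx) - 2),
                  .kmer_names(aa_alphabet(), 3))
}

#' Dipeptide deviation from expected mean (DDE)
#'
#' Standardized difference between the observed dipeptide composition
#' `D_c(x,y) = n_xy/(n-1)` and its codon-usage expectation
#' `T_m(x,y) = (C_x/C_n)(C_y/C_n)`, where `C_x` counts the codons encoding
#' residue x and `C_n = 61` is the codon total after removing the three stop
#' codons. The theoretical variance is `T_v = T_m(1 - T_m)/(n-1)` and
#' `DDE = (D_c - T_m)/sqrt(T_v)`. Values are signed and unbounded.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 400 (dipeptide order as in DPC).
#' @export
encode_dde <- function(seq) {
  .check_len(seq, 2, "DDE")
  idx <- .seq_index(seq)
  n <- length(idx)
  dc <- .kmer_counts(idx, 2, 20) / (n - 1)
  cc <- .codon_counts / 61
  tm <- as.vector(t(outer(cc, cc)))     # first-letter-major order
  tv <- tm * (1 - tm) / (n - 1)
  stats::setNames((dc - tm) / sqrt(tv), .kmer_names(aa_alphabet(), 2))
}

#' Grouped dipeptide composition (GDPC)
#'
#' Dipeptide composition computed after recoding residues into the five
#' physicochemical groups of [aa_groups_5()]: 25 features,
#' `f(x,y) = n_xy/(n-1)` with x, y group labels.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 25 (e.g. "g1g1", "g1g2", ...).
#' @export
encode_gdpc <- function(seq) {
  .check_len(seq, 2, "GDPC")
  g <- .group_index(seq, .aa_groups_5)
  stats::setNames(.kmer_counts(g, 2, 5) / (length(g) - 1),
                  .kmer_names(names(.aa_groups_5), 2))
}

#' Grouped tripeptide composition (GTPC)
#'
#' Tripeptide composition on the 5-group recoded sequence: 125 features,
#' `f(x,y,z) = n_xyz/(n-2)`.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 125.
#' @export
encode_gtpc <- function(seq) {
  .check_len(seq, 3, "GTPC")
  g <- .group_index(seq, .aa_groups_5)
  stats::setNames(.kmer_counts(g, 3, 5) / (length(g) - 2),
                  .kmer_names(names(.aa_groups_5), 3))
}

#' Composition of k-spaced amino acid group pairs (CKSAAGP)
#'
#' For each gap k = 0..max_gap, the frequencies of the 25 ordered group
#' pairs formed by residues k positions apart (k = 0 is adjacent, i.e. the
#' grouped dipeptide composition). Each gap block is normalized by its
#' n-k-1 windows, so each block sums to 1. Default max_gap = 5 gives
#' 150 features.
#'
#' @inheritParams encode_aac
#' @param max_gap Largest gap (number of skipped residues) to include.
#' @return Named numeric vector of length `25 * (max_gap + 1)`
#'   (e.g. "g1g2.gap0").
#' @export
encode_cksaagp <- function(seq, max_gap = 5) {
  stopifnot(max_gap >= 0)
  .check_len(seq, max_gap + 2, "CKSAAGP")
  g <- .group_index(seq, .aa_groups_5)
  n <- length(g)
  pair_names <- .kmer_names(names(.aa_groups_5), 2)
  out <- numeric(0)
  for (k in 0:max_gap) {
    a <- g[1:(n - k - 1)]
    b <- g[(k + 2):n]
    cnt <- tabulate((a - 1L) * 5L + b, nbins = 25)
    blk <- stats::setNames(cnt / (n - k - 1), paste0(pair_names, ".gap", k))
    out <- c(out, blk)
  }
  out
}

#' CTD composition (CTDC)
#'
#' For each of the 13 physicochemical properties of [ctd_properties()], the
#' fraction of residues falling in each of its three groups,
#' `C(x) = n(x)/n`. The three values of each property sum to 1; 39 features
#' in total.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 39 ("property.g1", ...).
#' @export
encode_ctdc <- function(seq) {
  .check_len(seq, 1, "CTDC")
  out <- numeric(0)
  for (p in names(.ctd_properties)) {
    g <- .group_index(seq, .ctd_properties[[p]])
    vals <- tabulate(g, 3) / length(g)
    out <- c(out, stats::setNames(vals, paste0(p, ".", c("g1", "g2", "g3"))))
  }
  out
}

#' CTD transition (CTDT)
#'
#' For each property, the frequency of adjacent residue pairs that cross
#' between two groups in either order:
#' `T(x,y) = (n(x,y) + n(y,x))/(n-1)` for the pairs (g1,g2), (g2,g3) and
#' (g3,g1); 39 features in total, each in [0, 1].
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 39 ("property.g1g2", ...).
#' @export
encode_ctdt <- function(seq) {
  .check_len(seq, 2, "CTDT")
  out <- numeric(0)
  pairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  pair_tok <- c("g1g2", "g2g3", "g3g1")
  for (p in names(.ctd_properties)) {
    g <- .group_index(seq, .ctd_properties[[p]])
    n <- length(g)
    a <- g[-n]
    b <- g[-1]
    vals <- vapply(pairs, function(pr) {
      sum((a == pr[1] & b == pr[2]) | (a == pr[2] & b == pr[1])) / (n - 1)
    }, numeric(1))
    out <- c(out, stats::setNames(vals, paste0(p, ".", pair_tok)))
  }
  out
}

#' Conjoint triad (CTriad)
#'
#' Frequencies of the 343 ordered class triples after recoding residues into
#' the seven conjoint-triad classes of [ctriad_classes()]; counts are taken
#' over the n-2 overlapping windows and reported as `count/(n-2)` (not
#' min-max rescaled), so the vector sums to 1.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 343 ("c1c1c1", ...).
#' @export
encode_ctriad <- function(seq) {
  .check_len(seq, 3, "CTriad")
  g <- .group_index(seq, .ctriad_classes)
  stats::setNames(.kmer_counts(g, 3, 7) / (length(g) - 2),
                  .kmer_names(names(.ctriad_classes), 3))
}

# Encoder registry: canonical tag, minimum sequence length, function.
.encoder_registry <- list(
  aac     = list(tag = "AAC",     min_len = 1, fun = function(s) encode_aac(s)),
  dpc     = list(tag = "DPC",     min_len = 2, fun = function(s) encode_dpc(s)),
  tpc     = list(tag = "TPC",     min_len = 3, fun = function(s) encode_tpc(s)),
  dde     = list(tag = "DDE",     min_len = 2, fun = function(s) encode_dde(s)),
  gdpc    = list(tag = "GDPC",    min_len = 2, fun = function(s) encode_gdpc(s)),
  gtpc    = list(tag = "GTPC",    min_len = 3, fun = function(s) encode_gtpc(s)),
  cksaagp = list(tag = "CKSAAGP", min_len = 7, fun = function(s) encode_cksaagp(s)),
  ctdc    = list(tag = "CTDC",    min_len = 1, fun = function(s) encode_ctdc(s)),
  ctdt    = list(tag = "CTDT",    min_len = 2, fun = function(s) encode_ctdt(s)),
  ctriad  = list(tag = "CTriad",  min_len = 3, fun = function(s) encode_ctriad(s))
)

#' Available encoder names
#'
#' @return Character vector of the lowercase encoder names accepted by
#'   [encode_dataset()].
#' @export
encoder_names <- function() names(.encoder_registry)

#' Encode a dataset into a feature matrix
#'
#' Applies one or more encoders to every sequence and concatenates the
#' resulting vectors column-wise, in request order. Column names are
#' prefixed with the encoder tag ("AAC:K", "DPC:LK", ...), making the
#' residue-level features stably addressable. All sequences must satisfy
#' the length precondition of every requested encoder.
#'
#' @param ds An `aa_dataset`.
#' @param encoders Character vector of encoder names (see [encoder_names()]).
#' @return A `feature_matrix`: list with `x` (numeric matrix, rows = sequence
#'   ids), `y` (integer label vector, possibly NA) and `encoders`.
#' @export
encode_dataset <- function(ds, encoders = "aac") {
  stopifnot(inherits(ds, "aa_dataset"), length(ds) > 0)
  encoders <- tolower(encoders)
  unknown <- setdiff(encoders, names(.encoder_registry))
  if (length(unknown) > 0) {
    stop("unknown encoder(s): ", paste(unknown, collapse = ", "),
         "; valid names: ", paste(encoder_names(), collapse = ", "))
  }
  lens <- nchar(ds$seq)
  for (e in encoders) {
    need <- .encoder_registry[[e]]$min_len
    short <- which(lens < need)
    if (length(short) > 0) {
      stop(sprintf("sequence '%s' (length %d) is too short for encoder %s (needs >= %d)",
                   ds$id[short[1]], lens[short[1]],
                   .encoder_registry[[e]]$tag, need))
    }
  }
  blocks <- lapply(encoders, function(e) {
    reg <- .encoder_registry[[e]]
    rows <- lapply(ds$seq, reg$fun)
    m <- do.call(rbind, rows)
    colnames(m) <- paste0(reg$tag, ":", names(rows[[1]]))
    m
  })
  x <- do.call(cbind, blocks)
  rownames(x) <- ds$id
  structure(list(x = x, y = ds$label, encoders = encoders),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d sequences x %d features [%s]\n",
              nrow(x$x), ncol(x$x), paste(x$encoders, collapse = "+")))
  if (any(!is.na(x$y))) {
    cat(sprintf("  labels: %d positive, %d negative\n",
                sum(x$y == 1L, na.rm = TRUE), sum(x$y == 0L, na.rm = TRUE)))
  }
  invisible(x)
}

#' Write a feature matrix to CSV
#'
#' First column `id`, then the named feature columns, and a final `label`
#' column when labels are present. Readable back with [read_feature_csv()].
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(id = rownames(fm$x), fm$x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (any(!is.na(fm$y))) df$label <- fm$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' @param path CSV written by [write_feature_csv()].
#' @return A `feature_matrix`.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("id" %in% names(df))
  has_label <- "label" %in% names(df)
  feat_cols <- setdiff(names(df), c("id", "label"))
  x <- as.matrix(df[, feat_cols, drop = FALSE])
  rownames(x) <- df$id
  y <- if (has_label) as.integer(df$label) else rep(NA_integer_, nrow(x))
  structure(list(x = x, y = y,
                 encoders = unique(tolower(sub(":.*$", "", feat_cols)))),
            class = "feature_matrix")
}

#' Write a feature matrix in LIBSVM sparse format
#'
#' One line per sequence: `label index:value ...` with 1-based feature
#' indices and zero-valued features omitted. Unlabeled rows get label 0.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_libsvm <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  lines <- vapply(seq_len(nrow(fm$x)), function(i) {
    v <- fm$x[i, ]
    nz <- which(v != 0)
    lab <- if (is.na(fm$y[i])) 0L else fm$y[i]
    paste(lab, paste(sprintf("%d:%.12g", nz, v[nz]), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
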