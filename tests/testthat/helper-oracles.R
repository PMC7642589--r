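# Independent naive-counting oracles for the descriptor encoders. These are
# deliberately written as direct window enumerations over character vectors
# (no shared code with the package implementation) so they can arbitrate.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

# all k-mers over `tokens`, first position slowest (lexicographic order)
all_kmers <- function(tokens, k) {
  out <- tokens
  if (k > 1) {
    for (i in 2:k) out <- as.vector(t(outer(out, tokens, paste0)))
  }
  out
}

oracle_aac <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  counts <- sapply(AA, function(a) sum(ch == a))
  counts / length(ch)
}

oracle_kmer_freq <- function(seq, k, tokens = AA) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  names <- all_kmers(tokens, k)
  counts <- setNames(numeric(length(names)), names)
  for (i in 1:(n - k + 1)) {
    w <- paste(ch[i:(i + k - 1)], collapse = "")
    counts[w] <- counts[w] + 1
  }
  counts / (n - k + 1)
}

oracle_dde <- function(seq) {
  cc <- c(A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2, I = 3, K = 2,
          L = 6, M = 1, N = 2, P = 4, Q = 2, R = 6, S = 6, T = 4, V = 4,
          W = 1, Y = 2)
  n <- nchar(seq)
  dc <- oracle_kmer_freq(seq, 2)
  out <- setNames(numeric(400), names(dc))
  for (d in names(dc)) {
    x <- substr(d, 1, 1); y <- substr(d, 2, 2)
    tm <- (cc[[x]] / 61) * (cc[[y]] / 61)
    tv <- tm * (1 - tm) / (n - 1)
    out[d] <- (dc[[d]] - tm) / sqrt(tv)
  }
  out
}

# recode a sequence into group labels under a named partition list
recode_groups <- function(seq, partition) {
  ch <- strsplit(seq, "")[[1]]
  sapply(ch, function(a) {
    for (g in names(partition)) if (a %in% partition[[g]]) return(g)
    stop("unmapped residue ", a)
  })
}

oracle_grouped_freq <- function(seq, k, partition) {
  g <- recode_groups(seq, partition)
  n <- length(g)
  names <- all_kmers(names(partition), k)
  counts <- setNames(numeric(length(names)), names)
  for (i in 1:(n - k + 1)) {
    w <- paste(g[i:(i + k - 1)], collapse = "")
    counts[w] <- counts[w] + 1
  }
  counts / (n - k + 1)
}

oracle_cksaagp <- function(seq, max_gap = 5) {
  partition <- thermoscan::aa_groups_5()
  g <- recode_groups(seq, partition)
  n <- length(g)
  pair_names <- all_kmers(names(partition), 2)
  out <- numeric(0)
  for (k in 0:max_gap) {
    counts <- setNames(numeric(25), pair_names)
    for (i in 1:(n - k - 1)) {
      w <- paste0(g[i], g[i + k + 1])
      counts[w] <- counts[w] + 1
    }
    out <- c(out, setNames(counts / (n - k - 1),
                           paste0(pair_names, ".gap", k)))
  }
  out
}

oracle_ctdc <- function(seq) {
  props <- thermoscan::ctd_properties()
  out <- numeric(0)
  for (p in names(props)) {
    g <- recode_groups(seq, props[[p]])
    vals <- sapply(c("g1", "g2", "g3"), function(gr) mean(g == gr))
    out <- c(out, setNames(vals, paste0(p, ".", c("g1", "g2", "g3"))))
  }
  out
}

oracle_ctdt <- function(seq) {
  props <- thermoscan::ctd_properties()
  pairs <- list(c("g1", "g2"), c("g2", "g3"), c("g3", "g1"))
  out <- numeric(0)
  for (p in names(props)) {
    g <- recode_groups(seq, props[[p]])
    n <- length(g)
    vals <- sapply(pairs, function(pr) {
      cnt <- 0
      for (i in 1:(n - 1)) {
        if ((g[i] == pr[1] && g[i + 1] == pr[2]) ||
            (g[i] == pr[2] && g[i + 1] == pr[1])) cnt <- cnt + 1
      }
      cnt / (n - 1)
    })
    out <- c(out, setNames(vals, paste0(p, ".", c("g1g2", "g2g3", "g3g1"))))
  }
  out
}

oracle_ctriad <- function(seq) {
  oracle_grouped_freq(seq, 3, thermoscan::ctriad_classes())
}

# dense PageRank power iteration on an explicit weight matrix (for fusion
# cross-checks); dangling mass redistributed uniformly
oracle_pagerank <- function(w, damping = 0.85, tol = 1e-14, iters = 100000) {
  n <- nrow(w)
  out_w <- rowSums(w)
  pr <- rep(1 / n, n)
  for (i in 1:iters) {
    new <- rep((1 - damping) / n, n)
    for (j in 1:n) {
      for (i2 in 1:n) {
        if (out_w[i2] > 0) {
          new[j] <- new[j] + damping * pr[i2] * w[i2, j] / out_w[i2]
        }
      }
      new[j] <- new[j] + damping * sum(pr[out_w == 0]) / n
    }
    if (sum(abs(new - pr)) < tol) return(new)
    pr <- new
  }
  pr
}
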