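test_that("AAC matches hand counts and sums to one", {
  v <- encode_aac("AAAA")
  expect_equal(unname(v["A"]), 1)
  expect_equal(sum(v), 1)
  v <- encode_aac("MKKD")
  expect_equal(unname(v[c("K", "M", "D")]), c(0.5, 0.25, 0.25))
  expect_equal(names(v), aa_alphabet())
  expect_error(encode_aac(""), "length")
})

test_that("DPC counts overlapping dipeptides over n-1 windows", {
  expect_equal(unname(encode_dpc("AAA")["AA"]), 1)
  v <- encode_dpc("MKKD")
  expect_equal(unname(v[c("MK", "KK", "KD")]), rep(1 / 3, 3))
  expect_equal(sum(v), 1)
  expect_error(encode_dpc("M"), ">= 2")
})

test_that("TPC counts overlapping tripeptides over n-2 windows", {
  expect_equal(unname(encode_tpc("AAAA")["AAA"]), 1)
  v <- encode_tpc("MKKDE")
  expect_equal(unname(v[c("MKK", "KKD", "KDE")]), rep(1 / 3, 3))
  expect_error(encode_tpc("MK"), ">= 3")
})

test_that("DDE evaluates the codon-expectation formulas", {
  # direct evaluation for the 2-residue case
  v <- encode_dde("AC")
  tm_ac <- (4 / 61) * (2 / 61)
  expect_equal(unname(v["AC"]), (1 - tm_ac) / sqrt(tm_ac * (1 - tm_ac)))
  tm_kk <- (2 / 61)^2
  expect_equal(unname(v["KK"]), (0 - tm_kk) / sqrt(tm_kk * (1 - tm_kk)))
  # sign property: sign(DDE) == sign(Dc - Tm) everywhere
  set.seed(3)
  s <- random_seq(80)
  dde <- encode_dde(s)
  dc <- oracle_kmer_freq(s, 2)
  cc <- codon_counts() / 61
  tm <- sapply(names(dc), function(d) cc[substr(d, 1, 1)] * cc[substr(d, 2, 2)])
  expect_equal(sign(unname(dde)), sign(unname(dc - tm)))
  # homopolymer: observed 1 far above expectation
  expect_gt(encode_dde(strrep("A", 400))["AA"], 0)
})

test_that("grouped encoders equal composition of the recoded sequence", {
  # sequence entirely in one group
  v <- encode_gdpc("GAVLMI")
  expect_equal(unname(v["g1g1"]), 1)
  v3 <- encode_gtpc("GAVLMI")
  expect_equal(unname(v3["g1g1g1"]), 1)
  expect_equal(sum(v3), 1)
  expect_error(encode_gtpc("GA"), ">= 3")
})

test_that("CKSAAGP gap-0 block reproduces GDPC and blocks sum to one", {
  set.seed(7)
  s <- random_seq(30)
  v <- encode_cksaagp(s)
  g0 <- v[grep("\\.gap0$", names(v))]
  expect_equal(unname(g0), unname(encode_gdpc(s)))
  for (k in 0:5) {
    expect_equal(sum(v[grep(paste0("\\.gap", k, "$"), names(v))]), 1)
  }
  expect_error(encode_cksaagp("MKKDE"), ">= 7")
})

test_that("CTDC sums to one within each property", {
  set.seed(8)
  v <- encode_ctdc(random_seq(40))
  for (p in names(ctd_properties())) {
    expect_equal(sum(v[paste0(p, ".", c("g1", "g2", "g3"))]), 1)
  }
  # all residues in group 1 of the charge property
  v <- encode_ctdc("KRKRKR")
  expect_equal(unname(v["charge.g1"]), 1)
})

test_that("CTDT counts between-group transitions in both orders", {
  # homogeneous group: no transitions anywhere for charge
  expect_equal(unname(encode_ctdt("KRKRKR")["charge.g1g2"]), 0)
  # alternating charge groups g1 (K) / g3 (D): all 5 adjacent pairs cross
  v <- encode_ctdt("KDKDKD")
  expect_equal(unname(v["charge.g3g1"]), 1)
  expect_equal(unname(v["charge.g1g2"]), 0)
})

test_that("CTriad counts 7-class triads over n-2 windows", {
  v <- encode_ctriad("AGV")  # all class c1
  expect_equal(unname(v["c1c1c1"]), 1)
  expect_equal(length(v), 343)
  expect_error(encode_ctriad("AG"), ">= 3")
})

test_that("encode_dataset concatenates encoder blocks with tag prefixes", {
  set.seed(9)
  ds <- aa_dataset(paste0("s", 1:5),
                   replicate(5, random_seq(sample(20:40, 1))),
                   c(1L, 1L, 0L, 0L, 0L))
  fm <- encode_dataset(ds, "aac")
  expect_equal(dim(fm$x), c(5, 20))
  fm2 <- encode_dataset(ds, c("aac", "dpc"))
  expect_equal(ncol(fm2$x), 420)
  expect_equal(colnames(fm2$x)[1:20], paste0("AAC:", aa_alphabet()))
  expect_true(all(startsWith(colnames(fm2$x)[21:420], "DPC:")))
  expect_equal(fm2$y, ds$label)
  # addressable residue-level features match the per-sequence encoders
  lk <- sapply(ds$seq, function(s) encode_dpc(s)["LK"])
  expect_equal(unname(fm2$x[, "DPC:LK"]), unname(lk))
})

test_that("encode_dataset names the offending sequence and encoder", {
  ds <- aa_dataset(c("ok", "tiny"), c("MKKDEFGH", "MK"))
  expect_error(encode_dataset(ds, "tpc"), "tiny.*TPC")
  expect_error(encode_dataset(ds, "bogus"), "unknown encoder")
})

test_that("feature CSV and LIBSVM writers round-trip / format correctly", {
  set.seed(10)
  ds <- aa_dataset(c("a", "b", "c"), replicate(3, random_seq(25)),
                   c(1L, 0L, 1L))
  fm <- encode_dataset(ds, c("aac", "gdpc"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fm, f)
  back <- read_feature_csv(f)
  expect_equal(back$x, fm$x)
  expect_equal(back$y, fm$y)
  # libsvm lines: label then 1-based index:value pairs
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_libsvm(fm, f2)
  lines <- readLines(f2)
  expect_length(lines, 3)
  expect_match(lines[1], "^1( \\d+:[0-9.eE+-]+)+$")
  first <- strsplit(lines[2], " ")[[1]]
  expect_equal(first[1], "0")
  idx1 <- as.integer(sub(":.*", "", first[2]))
  expect_equal(unname(fm$x[2, idx1]),
               as.numeric(sub(".*:", "", first[2])))
})
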