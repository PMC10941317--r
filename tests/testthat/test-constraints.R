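default_cs <- constraint_set()

test_that("gc_fraction counts G/C over the span, N counts as neither", {
  expect_equal(gc_fraction("ACGT"), 0.5)
  expect_equal(gc_fraction("AATT"), 0)
  expect_equal(gc_fraction("GGCC"), 1)
  expect_equal(gc_fraction("GCNN"), 0.5)
  expect_equal(gc_fraction("GGCCAA", c(0, 4)), 1)
  expect_error(gc_fraction("ACGT", c(2, 2)), "interval")
  expect_error(gc_fraction("ACGT", c(0, 5)), "interval")
})

test_that("the overlong-homopolymer example is flagged exactly as expected", {
  cs <- constraint_set(target_length = 30)
  s <- example_homopolymer_read()
  expect_identical(nchar(s), 32L)
  v <- find_violations(s, cs)
  expect_setequal(v$rule, c("homopolymer", "length"))
  hp <- v[v$rule == "homopolymer", ]
  expect_identical(c(hp$start, hp$end), c(5L, 10L))  # the run of five A
  expect_equal(hp$magnitude, 2)
  expect_equal(v$magnitude[v$rule == "length"], 2)
})

test_that("satisfying sequences yield no violations and zero error profile", {
  cs <- constraint_set(target_length = 30)
  s <- example_window_run_read()
  fixed <- s
  substr(fixed, 13, 13) <- "G"
  expect_identical(nrow(find_violations(fixed, cs)), 0L)
  ep <- error_profile(fixed, cs)
  expect_true(all(ep$scores == 0))
  expect_equal(ep$total, 0)
  expect_identical(ep$length_delta, 0L)
})

test_that("blacklist motifs are found at every overlapping occurrence", {
  cs <- constraint_set(gc_min = 0, gc_max = 1, blacklist = "CGTA")
  v <- find_violations("ACGTACGTACGT", cs)
  v <- v[v$rule == "blacklist", ]
  expect_identical(nrow(v), 2L)
  expect_identical(v$start, c(1L, 5L))
  expect_identical(v$end, c(5L, 9L))
  # overlapping motif occurrences both count
  cs2 <- constraint_set(gc_min = 0, gc_max = 1, max_homopolymer = 10, blacklist = "AA")
  v2 <- find_violations("AAA", cs2)
  expect_identical(sum(v2$rule == "blacklist"), 2L)
})

test_that("error metric contributions match their closed forms", {
  # run of 5 under h = 3: each run position scores (5-3)/5 = 0.4
  cs <- constraint_set(gc_min = 0, gc_max = 1, max_homopolymer = 3)
  ep <- error_profile("AAAAA", cs)
  expect_equal(ep$scores, rep(0.4, 5))
  expect_equal(ep$total, 2)

  # window at GC 0.8 against max 0.6: each G/C position scores 0.2
  cs <- constraint_set(gc_min = 0, gc_max = 1, window_size = 10,
                       gc_window_min = 0, gc_window_max = 0.6,
                       max_homopolymer = 10)
  s <- "GCGCGCGCAT"
  ep <- error_profile(s, cs)
  ch <- strsplit(s, "")[[1]]
  expect_equal(ep$scores[ch %in% c("G", "C")], rep(0.2, 8))
  expect_equal(ep$scores[ch %in% c("A", "T")], rep(0, 2))

  # too GC-poor: only A/T positions are charged
  cs <- constraint_set(gc_min = 0.5, gc_max = 1, window_size = 100)
  ep <- error_profile("AAAG", cs)
  expect_true(all(ep$scores[1:3] > 0))
  expect_equal(ep$scores[4], 0)
})

test_that("violation_penalty sums rule weights over violations", {
  cs <- constraint_set(target_length = 30)
  fixed <- example_window_run_read()
  substr(fixed, 13, 13) <- "G"
  expect_equal(violation_penalty(fixed, cs), 0)
  expect_equal(violation_penalty("AAAAA", constraint_set(gc_min = 0, gc_max = 1)), 1)
  cs2 <- constraint_set(gc_min = 0, gc_max = 1, blacklist = "CGTA",
                        rule_weights = c(blacklist = 0.5))
  expect_equal(violation_penalty("ACGTACGTACGT", cs2), 1)
})

test_that("N bases always violate through the dedicated rule", {
  cs <- constraint_set(gc_min = 0, gc_max = 1, max_homopolymer = 5)
  v <- find_violations("ACNGT", cs)
  expect_identical(v$rule, "ambiguous")
  expect_identical(c(v$start, v$end), c(2L, 3L))
  expect_equal(error_profile("ACNGT", cs)$scores[3], 1)
})

test_that("k-mer repeats beyond the allowed count are flagged", {
  cs <- constraint_set(gc_min = 0, gc_max = 1, max_homopolymer = 10,
                       kmer_k = 3, kmer_max_occurrences = 1)
  v <- find_violations("ACGTTACGT", cs)  # ACG and CGT occur twice each
  expect_identical(sort(unique(v$rule)), "kmer")
  expect_identical(nrow(v), 2L)
  expect_equal(v$magnitude, c(1, 1))
  # excess occurrences (beyond the first) carry the per-base score
  ep <- error_profile("ACGTTACGT", cs)
  expect_true(all(ep$scores[6:9] > 0))
  expect_true(all(ep$scores[1:3] == 0))
})

test_that("no violations iff zero error total and zero length delta", {
  set.seed(42)
  cs <- constraint_set(target_length = c(15, 25), blacklist = "GGATCC",
                       kmer_k = 8)
  for (i in 1:60) {
    s <- random_seq(sample(10:30, 1))
    v <- find_violations(s, cs)
    ep <- error_profile(s, cs)
    expect_identical(nrow(v) == 0L, ep$total == 0 && ep$length_delta == 0L)
  }
})

test_that("detection agrees with the naive brute-force scanners", {
  set.seed(101)
  css <- list(
    constraint_set(target_length = 40),
    constraint_set(gc_min = 0.3, gc_max = 0.7, window_size = 7,
                   max_homopolymer = 2, blacklist = c("ACGT", "TTAA"),
                   kmer_k = 4, kmer_max_occurrences = 2),
    constraint_set(window_size = 200, target_length = c(20, 60))
  )
  for (i in 1:100) {
    cs <- css[[(i %% length(css)) + 1L]]
    s <- random_seq(sample(1:120, 1),
                    alphabet = c(DNA, if (i %% 7 == 0) "N"))
    got <- sort_violations(find_violations(s, cs))
    want <- sort_violations(naive_violations(s, cs))
    expect_equal(got, want, info = paste("seq:", s))
    if (nrow(got)) {
      expect_true(all(got$start >= 0 & got$end <= nchar(s) & got$magnitude > 0))
    }
  }
})

test_that("extending a run at the homopolymer bound creates a violation", {
  cs <- constraint_set(gc_min = 0, gc_max = 1, max_homopolymer = 3)
  set.seed(5)
  for (i in 1:20) {
    base <- sample(DNA, 1)
    s <- paste0(random_seq(5), strrep(base, 3))
    before <- sum(find_violations(s, cs)$rule == "homopolymer")
    after <- find_violations(paste0(s, base), cs)
    after <- after[after$rule == "homopolymer", ]
    expect_gte(nrow(after), 1L)
    expect_true(any(after$end == nchar(s) + 1L))
  }
})

test_that("constraint_set rejects inconsistent parameters", {
  expect_error(constraint_set(gc_min = 0.7, gc_max = 0.3))
  expect_error(constraint_set(blacklist = "ACGX"), "blacklist")
  expect_error(constraint_set(rule_weights = c(nonsense = 1)), "unknown rule")
  expect_error(constraint_set(rule_weights = c(kmer = -1)), "non-negative")
  expect_error(constraint_set(target_length = c(30, 20)))
})
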