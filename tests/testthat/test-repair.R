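test_that("edit_distance matches an independent dynamic program", {
  expect_identical(edit_distance("ACGT", "ACGT"), 0L)
  expect_identical(edit_distance("ACGT", "AGT"), 1L)
  expect_identical(edit_distance("AAAA", "TTTT"), 4L)
  set.seed(21)
  for (i in 1:40) {
    a <- random_seq(sample(0:15, 1))
    b <- random_seq(sample(0:15, 1))
    expect_identical(edit_distance(a, b), as.integer(dp_edit_distance(a, b)))
  }
})

test_that("apply_edits replays substitutions, deletions and insertions", {
  edits <- rbind(
    data.frame(op = "substitution", pos = 1L, from = "C", to = "G"),
    data.frame(op = "deletion", pos = 3L, from = "T", to = NA),
    data.frame(op = "insertion", pos = 3L, from = NA, to = "A")
  )
  expect_identical(apply_edits("ACGT", edits), "AGGA")
  expect_error(apply_edits("ACGT", data.frame(op = "deletion", pos = 0L,
                                              from = "C", to = NA)))
})

test_that("an overlong read with a long run repairs to a compliant sequence", {
  cs <- constraint_set(target_length = 30)
  res <- repair_sequence(example_homopolymer_read(), cs)
  expect_true(res$success)
  expect_identical(nchar(res$repaired), 30L)
  expect_lte(max_homopolymer_run(res$repaired), 3L)
  expect_identical(nrow(find_violations(res$repaired, cs)), 0L)
  expect_identical(apply_edits(example_homopolymer_read(), res$edits), res$repaired)
})

test_that("a run crossing a GC window boundary is repaired with G", {
  cs <- constraint_set(target_length = 30)
  s <- example_window_run_read()
  res <- repair_sequence(s, cs)
  expect_true(res$success)
  expect_identical(res$n_changes, 1L)
  expect_identical(res$edits$op, "substitution")
  expect_identical(res$edits$to, "G")
  # brute force over the candidate bases at the edited position:
  # G is the unique valid single-base fix
  pos <- res$edits$pos + 1L
  valid_bases <- Filter(function(b) {
    cand <- s
    substr(cand, pos, pos) <- b
    naive_valid(cand, cs)
  }, setdiff(DNA, substr(s, pos, pos)))
  expect_identical(valid_bases, "G")
})

test_that("repair is an identity on valid input and deterministic otherwise", {
  cs <- constraint_set(target_length = 30)
  valid <- example_window_run_read()
  substr(valid, 13, 13) <- "G"
  res <- repair_sequence(valid, cs)
  expect_true(res$success)
  expect_identical(res$n_changes, 0L)
  expect_identical(res$repaired, valid)

  a <- repair_sequence(example_homopolymer_read(), cs)
  b <- repair_sequence(example_homopolymer_read(), cs)
  expect_identical(a$edits, b$edits)

  # idempotence: repairing a successful repair changes nothing
  again <- repair_sequence(a$repaired, cs)
  expect_identical(again$n_changes, 0L)
})

test_that("repair respects the edit budget and reports failure honestly", {
  cs <- constraint_set(target_length = 30)
  res <- repair_sequence(example_homopolymer_read(), cs, max_changes = 0L)
  expect_false(res$success)
  expect_identical(res$n_changes, 0L)
  res1 <- repair_sequence(example_homopolymer_read(), cs, max_changes = 2L)
  expect_false(res1$success)
  expect_lte(res1$n_changes, 2L)
})

test_that("successful repairs are sound on randomized corrupted input", {
  set.seed(77)
  cs <- constraint_set(target_length = 40)
  params <- channel_params(ref_length = 40, sub_rate = 0.05,
                           ins_rate = 0.02, del_rate = 0.02)
  for (i in 1:40) {
    ref <- generate_reference(cs, 40)
    read <- corrupt_read(ref, params)$bases
    res <- repair_sequence(read, cs, max_changes = 8L)
    expect_lte(res$n_changes, 8L)
    expect_identical(apply_edits(read, res$edits), res$repaired)
    if (res$success) {
      expect_identical(nrow(find_violations(res$repaired, cs)), 0L)
    }
  }
})

make_cluster <- function(centroid, members) {
  members$distance <- edit_distance(centroid$bases, members$bases)
  structure(list(id = "cluster_1", centroid = centroid, members = members,
                 status = NULL, chosen = NULL, repair = NULL),
            class = "oligo_cluster")
}

test_that("cluster repair selects correct / substituted / repaired as specified", {
  cs <- constraint_set(target_length = 30)
  valid <- example_window_run_read()
  substr(valid, 13, 13) <- "G"

  # centroid already valid -> correct, chosen is the centroid
  cen <- seq_records("c1", valid, abundance = 5L)
  cl <- repair_cluster(make_cluster(cen, cen), cs)
  expect_identical(cl$status, "correct")
  expect_identical(cl$chosen$bases, valid)
  expect_true("correct" %in% cl$chosen$tags[[1]])

  # centroid violating, second member valid -> substituted
  cen <- seq_records("c1", example_window_run_read(), abundance = 5L)
  mem <- bind_records(cen, seq_records("m1", valid, abundance = 2L))
  cl <- repair_cluster(make_cluster(cen, mem), cs)
  expect_identical(cl$status, "substituted")
  expect_identical(cl$chosen$id, "m1")
  expect_true("substituted" %in% cl$chosen$tags[[1]])

  # all violating: exhaustive mode picks the cheapest repair
  cen <- seq_records("c1", example_homopolymer_read(), abundance = 5L)  # 3 edits
  mem <- bind_records(cen, seq_records("m1", example_window_run_read(),  # 1 edit
                                       abundance = 2L))
  cl <- repair_cluster(make_cluster(cen, mem), cs)
  expect_identical(cl$status, "repaired")
  expect_identical(cl$repair$member_id, "m1")
  expect_true("repaired:1" %in% cl$chosen$tags[[1]])

  # first-success mode stops at the centroid (distance 0, repaired first)
  cl2 <- repair_cluster(make_cluster(cen, mem), cs, exhaustive = FALSE)
  expect_identical(cl2$repair$member_id, "c1")
  expect_true("repaired:3" %in% cl2$chosen$tags[[1]])

  # nothing repairable within the budget -> unrecoverable
  cen <- seq_records("c1", strrep("A", 30))
  cl3 <- repair_cluster(make_cluster(cen, cen), cs, max_changes = 1L)
  expect_identical(cl3$status, "unrecoverable")
  expect_null(cl3$chosen)

  expect_error(repair_cluster(make_cluster(cen, cen[0, ]), cs), "no members")
})

test_that("keep_original_option emits the documented record sets", {
  cs <- constraint_set(target_length = 30)
  cen <- seq_records("c1", example_homopolymer_read(), abundance = 5L)
  cl <- repair_cluster(make_cluster(cen, cen), cs)
  expect_identical(cl$status, "repaired")

  both <- keep_original_option(cl, keep_original = TRUE)
  expect_identical(nrow(both), 2L)
  expect_true("original" %in% both$tags[[1]])
  expect_true(any(grepl("^repaired:", both$tags[[2]])))

  one <- keep_original_option(cl, keep_original = FALSE)
  expect_identical(nrow(one), 1L)

  valid <- example_window_run_read(); substr(valid, 13, 13) <- "G"
  cenv <- seq_records("c1", valid)
  clv <- repair_cluster(make_cluster(cenv, cenv), cs)
  expect_identical(nrow(keep_original_option(clv, keep_original = TRUE)), 1L)
})

test_that("report entries mirror the cluster outcome", {
  cs <- constraint_set(target_length = 30)
  cen <- seq_records("c1", example_homopolymer_read())
  cl <- repair_cluster(make_cluster(cen, cen), cs)
  e <- cluster_report_entry(cl)
  expect_identical(e$category, "repaired")
  expect_identical(e$n_changes, length(e$edits))
  expect_identical(e$chosen, cl$chosen$bases)
  validate_report(repair_report("x", list(e)))
})
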