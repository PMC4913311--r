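# small shared fixture databank (3 folds x 2 members) built once per file
local_toydb <- local({
  td <- NULL
  function() {
    if (is.null(td)) td <<- make_toy_databank(n_folds = 3,
                                              members_per_fold = 2,
                                              length = 24, seed = 404,
                                              sasa_points = 240)
    td
  }
})

test_that("a single 30-residue chain yields a single record of length 30", {
  ch <- make_pb_backbone(strrep("m", 30), sequence = random_sequence(30, 2),
                         id = "solo")
  db <- build_databank(list(list(id = "solo", members = list(ch))),
                       sasa_points = 240)
  expect_equal(length(db$records), 1L)
  rec <- db$records[["solo"]]
  expect_equal(rec$length, 30L)
  expect_equal(length(rec$profile), 30)
  expect_equal(nchar(rec$pb), 30)
  expect_equal(rec$sequence, chain_sequence(ch))
})

test_that("family alignment rows must match member sequences", {
  ch <- make_pb_backbone(strrep("m", 20), sequence = strrep("A", 20))
  fam <- list(id = "bad", members = list(ch),
              alignment = paste0(strrep("A", 19), "C"))
  expect_error(build_databank(list(fam)), "alignment/sequence mismatch")
})

test_that("agreeing members give a near one-hot PB column", {
  seqs <- c(random_sequence(20, 31), random_sequence(20, 32))
  chains <- lapply(seq_along(seqs), function(k)
    make_pb_backbone(strrep("m", 20), sequence = seqs[k],
                     id = paste0("m", k)))
  fam <- list(id = "fam2", members = chains, alignment = seqs)
  db <- build_databank(list(fam), sasa_points = 240)
  prob <- db$records[["fam2"]]$profile$pb
  expect_gt(prob[10, "m"], 0.9)
  expect_true(all(abs(rowSums(prob) - 1) < 1e-9))
})

test_that("every record retrieves itself at rank 1 with perfect stats", {
  td <- local_toydb()
  for (id in names(td$databank$records)) {
    rec <- td$databank$records[[id]]
    res <- search_databank(rec$profile, td$databank, max_hits = 3)
    expect_equal(res$hits$id[1], id)
    expect_equal(res$hits$identity[1], 100)
    expect_equal(res$hits$coverage[1], 100)
  }
})

test_that("hit ranking is capped, descending, and order-independent", {
  td <- local_toydb()
  q <- td$databank$records[[1]]$profile
  res <- search_databank(q, td$databank, max_hits = 3)
  expect_equal(nrow(res$hits), 3L)
  expect_equal(res$hits$rank, 1:3)
  expect_true(!is.unsorted(rev(res$hits$score)))
  shuffled <- td$databank
  shuffled$records <- shuffled$records[rev(names(shuffled$records))]
  res2 <- search_databank(q, shuffled, max_hits = 3)
  expect_equal(res2$hits, res$hits)
  expect_error(search_databank(q, td$databank, max_hits = 0), "max_hits")
  expect_warning(
    search_databank(build_query_profile("ACDEF"), td$databank, max_hits = 1),
    "15-1000")
})

test_that("databank serialization reproduces in-memory search scores", {
  td <- local_toydb()
  dir <- tempfile("db_")
  write_databank(td$databank, dir)
  db2 <- read_databank(dir)
  expect_equal(names(db2$records), names(td$databank$records))
  q <- make_toy_query(td, "fold2", seed = 9, sasa_points = 240)$profile
  h1 <- search_databank(q, td$databank, max_hits = 6)$hits
  h2 <- search_databank(q, db2, max_hits = 6)$hits
  expect_equal(h2$id, h1$id)
  expect_equal(h2$score, h1$score, tolerance = 1e-4) # formatted at 6 decimals
  # round trip again: written files are stable
  dir2 <- tempfile("db_")
  write_databank(db2, dir2)
  expect_identical(readLines(file.path(dir, "templates.orp")),
                   readLines(file.path(dir2, "templates.orp")))
})

test_that("rendered alignments carry the annotation tracks", {
  td <- local_toydb()
  id <- names(td$databank$records)[1]
  rec <- td$databank$records[[id]]
  res <- search_databank(rec$profile, td$databank, max_hits = 1)
  txt <- render_alignment(res, td$databank, id = id, query_pb = rec$pb)
  match_line <- paste(sub("^match\\s+", "", grep("^match", txt, value = TRUE)),
                      collapse = "")
  expect_true(grepl("^\\|+$", gsub(" ", "", match_line)))
  # template PB 'm' positions render H in the SS track at the same column
  pbl <- sub("\\s+$", "", grep("^t_pb", txt, value = TRUE)[1])
  ssl <- sub("\\s+$", "", grep("^t_ss", txt, value = TRUE)[1])
  pbs <- strsplit(sub("^t_pb\\s+", "", pbl), "")[[1]]
  sss <- strsplit(sub("^t_ss\\s+", "", ssl), "")[[1]]
  expect_true(all(sss[pbs == "m"] == "H"))
  # block structure: 60 columns per block
  qlines <- grep("^query", txt, value = TRUE)
  expect_equal(length(qlines), ceiling(rec$length / 60))
})

test_that("hit tables round-trip through tsv and validate as json", {
  td <- local_toydb()
  rec <- td$databank$records[[2]]
  res <- search_databank(rec$profile, td$databank, max_hits = 4)
  f <- tempfile(fileext = ".tsv")
  write_hit_table(res, f)
  back <- read.delim(f)
  expect_equal(back$rank, res$hits$rank)
  expect_equal(back$id, res$hits$id)
  fj <- tempfile(fileext = ".json")
  write_hit_table(res, fj, format = "json")
  parsed <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(parsed$id, res$hits$id)
  expect_equal(names(parsed), names(res$hits))
  # zero hits: header-only file
  f0 <- tempfile(fileext = ".tsv")
  write_hit_table(res$hits[0, ], f0)
  expect_equal(length(readLines(f0)), 1L)
})
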