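# Annotation parsing, proteome table IO, STRING edge-list IO.

test_that("subunit annotations map oligomer vocabulary to k", {
  p <- parse_subunit_annotation(c(
    "Homotetramer.",
    "Heterodimer of subunits A and B.",
    "Homodimer; can also form homotetramers.",
    "Monomer.",
    "Homo-12-mer in the presence of zinc.",
    "Homooligomer.",
    "Interacts with the ribosome.",
    ""
  ))
  expect_equal(p$oligomer_k, c(4L, NA, 2L, 1L, 12L, NA, NA, NA))
  expect_equal(p$is_homo, c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, NA, NA))
  expect_equal(p$ambiguity_note[3], "2,4")
  expect_equal(p$ambiguity_note[1], "")
})

test_that("multi-state policy switches between first, min and max mention", {
  txt <- "Homotetramer; in low salt forms homodimers."
  expect_equal(parse_subunit_annotation(txt)$oligomer_k, 4L)  # first mention
  expect_equal(parse_subunit_annotation(txt, policy = "min")$oligomer_k, 2L)
  expect_equal(parse_subunit_annotation(txt, policy = "max")$oligomer_k, 4L)
})

test_that("first-mention policy agrees with the minimum-position oracle", {
  texts <- c("Homodimer; can also form homotetramers.",
             "Forms homohexamers, and rarely homodimers.",
             "Monomer; associates into homotetramers.")
  # oracle: list every homo-state mention with its position, take the
  # earliest
  oracle <- vapply(texts, function(s) {
    s <- tolower(s)
    terms <- c(monomer = 1, homodimer = 2, homotetramer = 4, homohexamer = 6)
    pos <- vapply(names(terms), function(t) regexpr(t, s, fixed = TRUE),
                  numeric(1))
    unname(terms[pos > 0][which.min(pos[pos > 0])])
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(as.numeric(parse_subunit_annotation(texts)$oligomer_k), oracle)
})

test_that("proteome tables round-trip and report malformed rows", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  rec <- make_records(c(1, 2, 4))
  write_proteome_table(rec, tmp)
  back <- read_proteome_table(tmp)
  attr(back, "n_malformed") <- NULL
  expect_equal(back, rec)

  # a zero oligomer_k violates the record invariant and is dropped
  bad <- rec
  bad$oligomer_k[2] <- 0L
  write_proteome_table(bad, tmp)
  expect_message(back2 <- read_proteome_table(tmp), "malformed")
  expect_equal(nrow(back2), 2L)
  expect_equal(attr(back2, "n_malformed"), 1L)
})

test_that("annotation column is parsed when oligomer_k is absent", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "protein_id\tlength_aa\tsubunit_annotation",
    "P1\t120\tHomotetramer.",
    "P2\t300\tHeterodimer of A and B.",
    "P3\t250\tMonomer."
  ), tmp)
  rec <- read_proteome_table(tmp)
  expect_equal(rec$oligomer_k, c(4L, NA, 1L))
  expect_equal(rec$is_homo, c(TRUE, FALSE, TRUE))
})

test_that("missing required proteome columns name the column", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("length_aa\toligomer_k", "100\t2"), tmp)
  expect_error(read_proteome_table(tmp), "protein_id",
               class = "homomer_format_error")
})

test_that("STRING edges deduplicate, drop self-pairs and honor score_min", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("ecoli_interaction_id_a", "ecoli_interaction_id_b",
          "ecoli_interaction_mode", "ecoli_interaction_action",
          "a_is_acting", "score", sep = "\t"),
    "A\tB\tbinding\tbinding\tf\t900",
    "B\tA\tbinding\tbinding\tf\t900",
    "A\tA\tbinding\tbinding\tf\t900"
  ), tmp)
  g <- read_string_edges(tmp, score_min = 0)
  expect_setequal(g$nodes, c("A", "B"))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(attr(g, "n_self_dropped"), 1L)

  writeLines(c(
    "ecoli_interaction_id_a\tecoli_interaction_id_b\tscore",
    "A\tB\t900", "A\tC\t500", "B\tC\t100", "C\tD\t50", "D\tE\t10"
  ), tmp)
  g2 <- read_string_edges(tmp, score_min = 100)
  expect_equal(nrow(g2$edges), 3L)

  writeLines("ecoli_interaction_id_a\tecoli_interaction_id_b\tscore", tmp)
  g3 <- read_string_edges(tmp)
  expect_equal(length(g3$nodes), 0L)
  expect_equal(nrow(g3$edges), 0L)

  writeLines(c("foo\tbar", "A\tB"), tmp)
  expect_error(read_string_edges(tmp), class = "homomer_format_error")
})

test_that("ppi_graph enforces its invariants", {
  expect_error(ppi_graph(c("A"), rbind(c("A", "A"))),
               class = "homomer_invalid_parameter")
  expect_error(ppi_graph(c("A", "B"), rbind(c("A", "B"), c("B", "A"))),
               class = "homomer_invalid_parameter")
  expect_error(ppi_graph(c("A", "B"), rbind(c("A", "C"))),
               class = "homomer_invalid_parameter")
})

test_that("random edge files always yield valid simple graphs", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  set.seed(99)
  for (i in 1:10) {
    ids <- sample(LETTERS[1:8], 40, replace = TRUE)
    df <- data.frame(ecoli_interaction_id_a = ids[1:20],
                     ecoli_interaction_id_b = ids[21:40],
                     score = sample(0:999, 20))
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    g <- tryCatch(read_string_edges(tmp, score_min = 300),
                  homomer_error = function(e) NULL)
    if (is.null(g) || nrow(g$edges) == 0) next
    expect_true(all(g$edges[, 1] != g$edges[, 2]))
    expect_false(anyDuplicated(paste(g$edges[, 1], g$edges[, 2])) > 0)
    expect_true(all(c(g$edges) %in% g$nodes))
  }
})
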