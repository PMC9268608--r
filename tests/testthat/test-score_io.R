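test_that("packaged score table has the documented shape and content", {
  tab <- example_score_table()
  expect_s3_class(tab, "score_table")
  expect_equal(nrow(tab), 60L)
  expect_equal(as.list(table(tab$group)),
               list(anti_apoptosis_survival = 7L,
                    cell_growth_proliferation = 22L,
                    metastasis = 10L,
                    signaling = 21L))
  # every score lies in the range spanned by the table extremes
  scores <- as.matrix(as.data.frame(tab)[, c(isomer_levels(),
                                             "inhibitor_score")])
  expect_true(all(scores >= -15 & scores <= -4))

  csf1r <- tab[tab$protein == "CSF1R", ]
  expect_equal(as.numeric(csf1r[, isomer_levels()]),
               c(-11.84, -9.29, -10.53, -10.40))
  expect_equal(csf1r$inhibitor, "Pexidartinib")
  expect_equal(csf1r$inhibitor_score, -11.59)
  expect_equal(csf1r$localization, "membrane")
})

test_that("score tables round-trip through write and load", {
  tab <- example_score_table()
  for (fmt in c("tsv", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_score_table(tab, path, format = fmt)
    back <- load_score_table(path, format = fmt)
    expect_equal(as.data.frame(back), as.data.frame(tab),
                 ignore_attr = "provenance")
  }
  gen <- generate_score_table(score_sim_config(proteins_per_group = 3,
                                               seed = 11))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(gen, path)
  back <- load_score_table(path)
  expect_equal(as.data.frame(back), as.data.frame(gen), tolerance = 1e-12,
               ignore_attr = "provenance")
})

test_that("malformed score tables are rejected with informative errors", {
  tab <- as.data.frame(example_score_table())

  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab[, setdiff(names(tab), "cis_plus")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_score_table(path), "cis_plus")

  bad <- tab
  bad$trans_minus <- as.character(bad$trans_minus)
  bad$trans_minus[3] <- "n/a"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_score_table(path), "row 3")

  dup <- rbind(tab, tab[1, ])
  write.table(dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_score_table(path), "duplicate")

  inf <- tab
  inf$cis_minus[5] <- Inf
  expect_error(score_table(inf), "non-finite")
})

test_that("interaction tables load into aggregated per-pose profiles", {
  profiles <- example_interaction_profiles()
  tm <- find_profile(profiles, "CSF1R", "trans_minus")
  expect_equal(tm$interactions$pi_pi, "Trp550")
  expect_setequal(tm$interactions$hydrogen_bond,
                  c("Tyr546", "Arg549", "Trp550"))
  expect_equal(tm$interactions$hydrophobic, character(0))

  erl <- find_profile(profiles, "EGFR", "erlotinib")  # case-insensitive
  expect_setequal(erl$interactions$hydrogen_bond, c("Asp855", "Phe856"))

  expect_null(find_profile(profiles, "CSF1R", "no_such_ligand"))
})

test_that("interaction table validation catches bad types and labels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein\tligand\tinteraction_type\tresidues",
               "P1\tL1\tsalt_bridge\tArg10"), path)
  expect_error(load_interaction_table(path), "salt_bridge")
  writeLines(c("protein\tligand\tinteraction_type\tresidues",
               "P1\tL1\thydrogen_bond\tArgX"), path)
  expect_error(load_interaction_table(path), "ArgX")
  # empty residue field gives an empty set
  writeLines(c("protein\tligand\tinteraction_type\tresidues",
               "P1\tL1\thydrogen_bond\t"), path)
  prof <- load_interaction_table(path)[[1]]
  expect_equal(prof$interactions$hydrogen_bond, character(0))
})

test_that("residue labels parse, canonicalise and round-trip", {
  p <- parse_residue("TRP550")
  expect_equal(p$code, "Trp")
  expect_equal(p$number, 550L)
  expect_equal(format_residue("trp550"), "Trp550")
  # round trip over every label in the packaged interaction table
  profiles <- example_interaction_profiles()
  labels <- unique(unlist(lapply(profiles,
                                 function(p) unlist(p$interactions))))
  expect_gt(length(labels), 10)
  expect_equal(format_residue(labels), labels)
  expect_error(parse_residue("550Trp"), "unparseable")
})

test_that("JSON results are stable-ordered and round-trip", {
  tab <- example_score_table()
  summ <- summarize_group(tab, "metastasis")
  path <- withr::local_tempfile(fileext = ".json")
  write_results(unclass(summ), path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_setequal(names(back),
                  c("group", "n_proteins", "sum_scores", "weighted_sums",
                    "preferred_isomer", "tie", "tied_isomers"))
  expect_equal(unlist(back$weighted_sums[isomer_levels()]),
               unlist(as.list(summ$weighted_sums)))
  # byte-identical on rewrite
  path2 <- withr::local_tempfile(fileext = ".json")
  write_results(unclass(summ), path2)
  expect_identical(readLines(path), readLines(path2))
  # empty collection is a valid empty JSON array
  path3 <- withr::local_tempfile(fileext = ".json")
  write_results(list(), path3)
  expect_equal(jsonlite::read_json(path3), list())

  # per-protein rank vectors survive a CSV round trip
  rt <- rank_table(tab)
  path4 <- withr::local_tempfile(fileext = ".csv")
  write_results(rt, path4, format = "csv")
  back4 <- read.csv(path4, stringsAsFactors = FALSE)
  expect_equal(back4$weighted_trans_minus, rt$weighted_trans_minus)
})
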