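members_table <- function() {
  mem <- load_fixture("antigen_members")
  residue_table(mem[, c("allele", "pos103", "pos109", "pos96")])
}

test_that("alleles sharing a prototype's DEP signature are assigned FULL", {
  reg <- default_registry()
  tbl <- members_table()
  # restrict to the B35 family so the partial (103/109-only) fixture
  # uniquely identifies each antigen
  cat_df <- data.frame(antigen = c("B-3501", "B-3512"),
                       prototype = c("B*35:01", "B*35:12"))
  ants <- antigen_set(cat_df, reg, tbl)
  a <- assign_allele(reg, tbl, "B*35:17", ants)
  expect_equal(a$antigen, "B-3512")
  expect_equal(a$category, "FULL")
  # prototype assigns to itself
  expect_equal(assign_allele(reg, tbl, "B*35:01", ants)$antigen, "B-3501")
  # no matching signature -> UNASSIGNED (B*35:02 carries 109F)
  u <- assign_allele(reg, tbl, "B*35:02", ants)
  expect_equal(u$category, "UNASSIGNED")
  expect_true(is.na(u$antigen))
})

test_that("unknown residues at required positions yield INCOMPLETE", {
  reg <- default_registry()
  tbl <- residue_table(data.frame(allele = c("B*35:01", "B*35:99"),
                                  pos103 = c("L", NA),
                                  pos109 = c("L", "L")))
  ants <- antigen_set(data.frame(antigen = "B-3501", prototype = "B*35:01"),
                      reg, tbl)
  a <- assign_allele(reg, tbl, "B*35:99", ants)
  expect_equal(a$category, "INCOMPLETE")
  expect_equal(a$mismatched_positions, "103")
})

test_that("pending positions downgrade FULL to SEROTYPE by config only", {
  reg <- default_registry()
  reg$pending$classI <- c("103")
  tbl <- members_table()
  ants <- antigen_set(data.frame(antigen = "B-5501", prototype = "B*55:01"),
                      reg, tbl)
  # B*55:04 differs from the prototype only at 103 (V vs L)
  a <- assign_allele(reg, tbl, "B*55:04", ants)
  expect_equal(a$category, "SEROTYPE")
  expect_equal(a$mismatched_positions, "103")
  # with an up-to-date (empty) pending set the same allele is unassigned
  reg$pending$classI <- character(0)
  expect_equal(assign_allele(reg, tbl, "B*55:04", ants)$category, "UNASSIGNED")
})

test_that("assignment is deterministic and blind to allele-set order", {
  reg <- default_registry()
  tbl <- members_table()
  cat_df <- load_fixture("previous_antigens")
  ants <- antigen_set(cat_df, reg, tbl)
  res1 <- assign_alleles(reg, tbl, ants)
  res2 <- assign_alleles(reg, tbl, ants, alleles = rev(tbl$allele))
  res2 <- res2[match(res1$allele, res2$allele), ]
  rownames(res2) <- NULL
  expect_equal(res1, res2)
  # idempotence
  expect_equal(assign_allele(reg, tbl, "B*56:03", ants),
               assign_allele(reg, tbl, "B*56:03", ants))
  # identical signatures receive the same antigen
  sigs <- vapply(tbl$allele, function(a)
    paste(dep_signature(reg, tbl, a)[c("103", "109")], collapse = "|"),
    character(1))
  for (s in unique(sigs[allele_locus(tbl$allele) == "B"])) {
    grpa <- res1$antigen[match(tbl$allele[sigs == s &
      allele_locus(tbl$allele) == "B"], res1$allele)]
    expect_length(unique(grpa), 1L)
  }
})

test_that("summarize_catalogue counts categories per locus", {
  reg <- default_registry()
  tbl <- members_table()
  ants <- antigen_set(load_fixture("previous_antigens"), reg, tbl)
  res <- assign_alleles(reg, tbl, ants)
  s <- summarize_catalogue(res)
  expect_equal(sum(s$total), nrow(res))
  expect_equal(s$total, s$FULL + s$SEROTYPE + s$INCOMPLETE + s$UNASSIGNED)
  # all 17 prototypes themselves assign FULL
  protos <- allele_key(load_fixture("previous_antigens")$prototype)
  expect_true(all(res$category[match(protos, res$allele)] == "FULL"))
  # empty input
  expect_equal(nrow(summarize_catalogue(res[0, ])), 0L)
  # a lone unknown-residue allele is INCOMPLETE
  tbl1 <- residue_table(data.frame(allele = c("B*35:01", "B*01:01"),
                                   pos103 = c("L", NA), pos109 = c("L", "L")))
  ants1 <- antigen_set(data.frame(antigen = "B-3501", prototype = "B*35:01"),
                       reg, tbl1)
  s1 <- summarize_catalogue(assign_alleles(reg, tbl1, ants1,
                                           alleles = "B*01:01"))
  expect_equal(s1$INCOMPLETE, 1L)
})

test_that("antigen_set rejects prototypes missing from the residue store", {
  reg <- default_registry()
  tbl <- members_table()
  expect_error(antigen_set(data.frame(antigen = "B-9901",
                                      prototype = "B*99:01"), reg, tbl),
               "B\\*99:01")
})

test_that("antigen splitting emits one proposal per new residue class", {
  reg_after <- default_registry()
  reg_before <- registry_without_positions(reg_after, "classI",
                                           c("103", "109"))
  reg_before <- registry_without_positions(reg_before, "DPB1", "96")
  mem <- load_fixture("antigen_members")
  tbl <- members_table()
  cat_df <- load_fixture("previous_antigens")
  props <- propose_new_antigens(reg_before, reg_after, tbl, cat_df,
                                membership = mem[, c("allele", "antigen")])
  expect_equal(sum(props$locus == "B"), 13L)
  expect_equal(sum(props$locus == "DPB1"), 5L)
  # the prototype's class keeps the previous name: no proposal is ever
  # named after a previous prototype
  expect_false(any(props$proposed %in% cat_df$antigen))
  # naming follows the hyphenated lowest-numbered-member convention
  expect_true("B-3521" %in% props$proposed)  # B*35:21 beats B*78:xx ordering
  expect_equal(props$dep1[props$proposed == "B-3502"], "109F")
  expect_equal(props$dep2[props$proposed == "B-3502"], "109L")
})

test_that("splitting with no divided class or derived membership behaves", {
  reg_after <- default_registry()
  reg_before <- registry_without_positions(reg_after, "classI", "109")
  # members that all share 109L: adding 109 must propose nothing
  tbl <- residue_table(data.frame(allele = c("B*07:02", "B*07:05"),
                                  pos103 = c("V", "V"),
                                  pos109 = c("L", "L")))
  props <- propose_new_antigens(reg_before, reg_after, tbl,
                                data.frame(antigen = "B-0702",
                                           prototype = "B*07:02"),
                                membership = data.frame(
                                  allele = c("B*07:02", "B*07:05"),
                                  antigen = "B-0702"))
  expect_equal(nrow(props), 0L)
  # membership can also be derived by assignment under the old registry
  tbl2 <- residue_table(data.frame(allele = c("B*35:01", "B*35:02"),
                                   pos103 = c("L", "L"),
                                   pos109 = c("L", "F")))
  props2 <- propose_new_antigens(reg_before, reg_after, tbl2,
                                 data.frame(antigen = "B-3501",
                                            prototype = "B*35:01"))
  expect_equal(props2$proposed, "B-3502")
  expect_equal(props2$splitting_positions, "109")
  # a missing prototype is reported by name
  expect_error(propose_new_antigens(reg_before, reg_after, tbl2,
                                    data.frame(antigen = "B-0801",
                                               prototype = "B*08:01")),
               "B\\*08:01")
})
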