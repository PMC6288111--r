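# Lipid shorthand parsing, annotation-level conversion and cross-platform
# matching.

test_that("the parser infers class, level and sum composition from syntax", {
  tg <- parseLipidName("TAG(16:0/18:1/18:2)")
  expect_s4_class(tg, "LipidName")
  expect_identical(lipidClass(tg), "TAG")
  expect_identical(annotationLevel(tg), "FULL_FA")
  expect_identical(unname(sumComposition(tg)), c(52L, 3L))
  expect_identical(chains(tg)$carbons, c(16L, 18L, 18L))
  expect_identical(chains(tg)$double_bonds, c(0L, 1L, 2L))

  sm <- parseLipidName("SM(d38:1)")
  expect_identical(lipidClass(sm), "SM")
  expect_identical(annotationLevel(sm), "SUM")
  expect_true(sm@sphingoidPrefix)
  expect_identical(unname(sumComposition(sm)), c(38L, 1L))

  tf <- parseLipidName("TAG52:3-FA16:0")
  expect_identical(annotationLevel(tf), "TAG_FA")
  expect_identical(unname(sumComposition(tf)), c(52L, 3L))
  expect_identical(chains(tf)$carbons, 16L)

  # sum-level, implied N-acyl and ether forms
  expect_identical(annotationLevel(parseLipidName("PC(34:1)")), "SUM")
  expect_identical(annotationLevel(parseLipidName("SM(20:0)")), "SM_IMPLIED")
  expect_identical(parseLipidName("PC(O-34:1)")@etherSum, "O")
  # deuterated internal standards keep their label
  expect_identical(parseLipidName("d5-TAG(17:0/17:0/17:1)")@deuterium, 5L)
})

test_that("class aliases are canonicalized and chain order never matters", {
  expect_identical(lipidClass(parseLipidName("TG(16:0/18:1/18:2)")), "TAG")
  expect_identical(lipidClass(parseLipidName("FA(18:1)")), "FFA")
  a <- parseLipidName("PC(18:1/16:0)")
  b <- parseLipidName("PC(16:0/18:1)")
  expect_true(sameLipid(a, b))
  expect_identical(formatLipidName(a), "PC(16:0/18:1)")
})

test_that("malformed names raise parse errors naming the offending token", {
  expect_error(parseLipidName("TAG(16:0/18:1)"), class = "lipidParseError")
  expect_error(parseLipidName("XYZ(16:0)"), class = "lipidParseError")
  expect_error(parseLipidName("PC(16:0/18:1/18:2)"), class = "lipidParseError")
  expect_error(parseLipidName("PC(16:20)"), class = "lipidParseError")
  expect_error(parseLipidName(""), class = "lipidParseError")
  expect_error(parseLipidName("PC(garbage)"),
               regexp = "garbage", class = "lipidParseError")
  expect_error(parseLipidName("PE(d34:1)"), class = "lipidParseError")
})

test_that("formatting then re-parsing is the identity on accepted names", {
  nl <- generateNameList(smallConfig(seed = 9L))
  pool <- c(nl$platform_a, nl$platform_b, "PC(O-34:1)", "SM(d40:2)",
            "d5-TAG(17:0/17:0/17:1)", "d9-CE(18:0)", "TAG50:2-FA18:1")
  for (nm in pool) {
    p1 <- parseLipidName(nm)
    p2 <- parseLipidName(formatLipidName(p1))
    expect_true(sameLipid(p1, p2), info = nm)
  }
})

test_that("TAG conversion yields one annotation per distinct fatty acid", {
  out <- convertToTargetLevel("TAG(16:0/18:1/18:2)")
  expect_setequal(canonicalText(out),
                  c("TAG52:3-FA16:0", "TAG52:3-FA18:1", "TAG52:3-FA18:2"))
  # duplicate chains collapse
  expect_identical(canonicalText(convertToTargetLevel("TAG(16:0/16:0/16:0)")),
                   "TAG48:0-FA16:0")
  # conversion cardinality stays within 1..3 over a generated panel
  nl <- generateNameList(smallConfig(seed = 5L))
  tags <- grep("^TAG\\(", nl$platform_a, value = TRUE)
  for (nm in tags) {
    n <- length(convertToTargetLevel(nm))
    expect_gte(n, 1L); expect_lte(n, 3L)
  }
})

test_that("sphingolipid sums convert by subtracting the d18:1 backbone", {
  expect_identical(canonicalText(convertToTargetLevel("SM(d38:1)")),
                   "SM(20:0)")
  expect_identical(canonicalText(convertToTargetLevel("CER(d34:1)")),
                   "CER(16:0)")
  # backbone subtraction impossible
  expect_error(convertToTargetLevel("SM(d18:1)"),
               class = "lipidConversionError")
  expect_error(convertToTargetLevel("SM(d20:0)"),
               class = "lipidConversionError")
})

test_that("converting an already-target-level set is the identity", {
  names <- c("TAG52:3-FA16:0", "SM(20:0)", "PC(16:0/18:1)", "LPC(18:0)",
             "CE(18:2)", "PC(O-34:1)")
  once <- convertNameSet(names)
  twice <- convertNameSet(canonicalText(once))
  expect_identical(canonicalText(once), canonicalText(twice))
  expect_identical(canonicalText(once), names)
})

test_that("name-set conversion deduplicates globally", {
  # two TAG sharing the 52:3 sum and the 16:0 anchor: 3 + 3 with one overlap
  out <- convertNameSet(c("TAG(16:0/18:1/18:2)", "TAG(16:0/18:0/18:3)"))
  expect_length(out, 5L)
  expect_length(convertNameSet(character(0)), 0L)
  expect_error(convertNameSet(c("PC(34:1)", "SM(d18:1)")),
               regexp = "SM\\(d18:1\\)", class = "lipidConversionError")
})

test_that("matching is symmetric, conserves the Venn triple and honours
           chain multisets", {
  a <- convertNameSet("PC(16:0/18:1)")
  b <- convertNameSet("PC(18:1/16:0)")
  expect_identical(matchAnnotations(a, b)$venn[["shared"]], 1L)

  nl <- generateNameList(smallConfig(seed = 3L))
  sa <- convertNameSet(nl$platform_a)
  sb <- convertNameSet(nl$platform_b)
  ov <- matchAnnotations(sa, sb)
  vo <- matchAnnotations(sb, sa)
  expect_identical(ov$venn[["shared"]], vo$venn[["shared"]])
  expect_identical(ov$venn[["a_only"]], vo$venn[["b_only"]])
  expect_identical(sum(ov$venn), ov$n_union)
  expect_identical(ov$n_union,
                   length(union(canonicalText(sa), canonicalText(sb))))
  # identity
  self <- matchAnnotations(sa, sa)
  expect_identical(self$venn[["shared"]], length(sa))
  expect_identical(self$venn[["a_only"]], 0L)
  # per-class counts tally with the totals
  expect_identical(sum(self$per_class$n_shared), length(sa))
})

test_that("ether-linked chains never match ester-linked chains and labeled
           standards are excluded from endogenous matching", {
  a <- convertNameSet(c("PC(O-16:0/18:1)", "PC(O-34:1)"))
  b <- convertNameSet(c("PC(16:0/18:1)", "PC(34:1)"))
  expect_identical(matchAnnotations(a, b)$venn[["shared"]], 0L)

  a2 <- convertNameSet(c("d5-TAG(17:0/17:0/17:1)", "PC(34:1)"))
  b2 <- convertNameSet(c("d5-TAG(17:0/17:0/17:1)", "PC(34:1)"))
  ov <- matchAnnotations(a2, b2)
  expect_identical(ov$venn[["shared"]], 1L)  # only the endogenous PC
  expect_identical(matchAnnotations(a2, b2, includeLabeled = TRUE)$venn[["shared"]], 3L)
})

test_that("convert-then-match equals brute-force pairwise comparison", {
  nl <- generateNameList(smallConfig(seed = 13L))
  sa <- convertNameSet(nl$platform_a)
  sb <- convertNameSet(nl$platform_b)
  ov <- matchAnnotations(sa, sb)
  # oracle: O(n^2) comparison of canonical strings
  brute <- sum(vapply(canonicalText(sa), function(x)
    any(x == canonicalText(sb)), logical(1)))
  expect_identical(ov$venn[["shared"]], as.integer(brute))
})

test_that("name lists and overlap reports round-trip through files", {
  tmp <- withr::local_tempdir()
  names <- c("TAG(16:0/18:1/18:2)", "PC(34:1)", "SM(d38:1)")
  writeLines(c("lipid_name", names), file.path(tmp, "names.txt"))
  expect_identical(readNameList(file.path(tmp, "names.txt")), names)
  writeLines(names, file.path(tmp, "bare.txt"))
  expect_identical(readNameList(file.path(tmp, "bare.txt")), names)

  ov <- matchAnnotations(convertNameSet(names),
                         convertNameSet(c("TAG52:3-FA16:0", "SM(20:0)")))
  path <- file.path(tmp, "overlap.csv")
  writeOverlapReport(ov, path)
  rep <- read.csv(path)
  expect_identical(nrow(rep), ov$n_union)
  expect_identical(sum(rep$in_platform_a & rep$in_platform_b),
                   ov$venn[["shared"]])
})
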