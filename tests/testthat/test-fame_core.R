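test_that("shorthand parser handles the printed notation dialects", {
  cases <- list(
    list("C18:1n9t", 18L, 1L, 9L, "trans", NA),
    list("16:1n7c", 16L, 1L, 7L, "cis", NA),
    list("C18:2ω6", 18L, 2L, 6L, "unspecified", NA),
    list("C16:0", 16L, 0L, NA, "unspecified", NA),
    list("C18:3 alpha", 18L, 3L, NA, "unspecified", "alpha"),
    list("C20:3c", 20L, 3L, NA, "cis", NA),
    list("C20:3t", 20L, 3L, NA, "trans", NA))
  for (cs in cases) {
    sp <- parse_fame_notation(cs[[1]])
    expect_equal(sp$carbons, cs[[2]], info = cs[[1]])
    expect_equal(sp$double_bonds, cs[[3]], info = cs[[1]])
    expect_equal(sp$omega, as.integer(cs[[4]]), info = cs[[1]])
    expect_equal(sp$geometry, cs[[5]], info = cs[[1]])
    expect_equal(sp$qualifier, as.character(cs[[6]]), info = cs[[1]])
  }
})

test_that("malformed tokens raise parse errors naming the token", {
  expect_error(parse_fame_notation("C1:5"), "C1:5",
               class = "famefuel_parse_error")
  expect_error(parse_fame_notation("C18:18"), class = "famefuel_parse_error")
  expect_error(parse_fame_notation("abc"), "abc",
               class = "famefuel_parse_error")
  expect_error(parse_fame_notation(""), class = "famefuel_parse_error")
  expect_error(parse_fame_notation("C:1"), class = "famefuel_parse_error")
})

test_that("canonical form round-trips for printed and fuzzed tokens", {
  reparse_equal <- function(token) {
    sp <- parse_fame_notation(token)
    sp2 <- parse_fame_notation(format_fame_notation(sp))
    identical(sp[c("carbons", "double_bonds", "omega", "geometry",
                   "qualifier")],
              sp2[c("carbons", "double_bonds", "omega", "geometry",
                    "qualifier")])
  }
  for (token in table2_tokens()) {
    expect_true(reparse_equal(token), info = token)
  }
  set.seed(42)
  for (i in 1:200) {
    rt <- random_token()
    sp <- parse_fame_notation(rt$token)
    expect_equal(sp$carbons, rt$carbons, info = rt$token)
    expect_equal(sp$double_bonds, rt$bonds, info = rt$token)
    expect_equal(sp$geometry, rt$geometry, info = rt$token)
    expect_true(reparse_equal(rt$token), info = rt$token)
  }
})

test_that("methyl-ester molecular weights match the atom-count oracle", {
  expect_equal(fame_molecular_weight(parse_fame_notation("C16:0")), 270.45,
               tolerance = 0.01 / 270.45)
  expect_equal(fame_molecular_weight(18, 1), 296.49,
               tolerance = 0.01 / 296.49)
  expect_equal(fame_molecular_weight(2, 0), 74.08, tolerance = 0.01 / 74.08)
  set.seed(7)
  for (i in 1:100) {
    carbons <- sample(2:30, 1)
    bonds <- sample(0:(carbons - 1), 1)
    expect_equal(fame_molecular_weight(carbons, bonds),
                 oracle_mw(carbons, bonds), tolerance = 1e-6 / 300)
  }
})

test_that("saturation classes follow the double-bond count", {
  expect_equal(saturation_class(parse_fame_notation("C18:0")), "SFA")
  expect_equal(saturation_class(parse_fame_notation("C18:1n9t")), "MUFA")
  expect_equal(saturation_class(parse_fame_notation("C22:6")), "PUFA")
  expect_equal(saturation_class(c(0L, 1L, 2L, 5L)),
               c("SFA", "MUFA", "PUFA", "PUFA"))
})

test_that("class totals reproduce the printed PW column", {
  pw <- table2_profiles()[["PW"]]
  totals <- class_totals(pw)
  expect_equal(round(totals$sfa, 1), 30.9)
  expect_equal(round(totals$mufa, 1), 42.6)
  expect_equal(round(totals$pufa, 1), 23.5)
  expect_equal(round(totals$sfa_ufa_ratio, 2), 0.47)
  # every species accounted for, no renormalization
  expect_lt(abs(sum(pw$species$weight_percent) -
                  (totals$sfa + totals$mufa + totals$pufa)), 1e-9)
  bg <- table2_profiles()[["BG-11"]]
  tb <- class_totals(bg)
  expect_equal(round(tb$sfa, 1), 33.7)
  expect_equal(round(tb$mufa, 1), 41.1)
  expect_equal(round(tb$pufa, 1), 23.3)
  expect_lt(abs(sum(bg$species$weight_percent) -
                  (tb$sfa + tb$mufa + tb$pufa)), 1e-9)
})

test_that("class totals are permutation-invariant and additive", {
  pw <- table2_profiles()[["PW"]]
  set.seed(11)
  for (i in 1:5) {
    perm <- sample(nrow(pw$species))
    shuffled <- fame_profile("perm", Map(parse_fame_notation,
                                         pw$species$notation[perm],
                                         pw$species$weight_percent[perm]))
    expect_equal(unclass(class_totals(shuffled))[c("sfa", "mufa", "pufa")],
                 unclass(class_totals(pw))[c("sfa", "mufa", "pufa")])
  }
  # additivity over a disjoint split of the species set
  idx <- seq_len(nrow(pw$species)) <= 4
  part <- function(sel) fame_profile("part", Map(
    parse_fame_notation, pw$species$notation[sel],
    pw$species$weight_percent[sel]))
  ta <- class_totals(part(idx)); tb <- class_totals(part(!idx))
  tw <- class_totals(pw)
  expect_equal(ta$sfa + tb$sfa, tw$sfa)
  expect_equal(ta$mufa + tb$mufa, tw$mufa)
  expect_equal(ta$pufa + tb$pufa, tw$pufa)
})

test_that("degenerate profiles are handled: empty and all-saturated", {
  empty <- fame_profile("empty", list())
  t0 <- class_totals(empty)
  expect_equal(c(t0$sfa, t0$mufa, t0$pufa, t0$ufa), c(0, 0, 0, 0))
  expect_false(t0$ratio_defined)
  expect_true(is.na(t0$sfa_ufa_ratio))
  sat <- fame_profile("sfa", list(parse_fame_notation("C16:0", 60),
                                  parse_fame_notation("C18:0", 40)))
  ts <- class_totals(sat)
  expect_false(ts$ratio_defined)
  expect_equal(ts$sfa, 100)
})

test_that("profile validation rejects duplicates and excess totals", {
  expect_error(
    fame_profile("dup", list(parse_fame_notation("C16:0", 10),
                             parse_fame_notation("16:0", 20))),
    class = "famefuel_profile_error")
  expect_error(
    fame_profile("over", list(parse_fame_notation("C16:0", 70),
                              parse_fame_notation("C18:0", 40))),
    class = "famefuel_profile_error")
  # a total just inside the 0.5 tolerance is accepted
  expect_s3_class(
    fame_profile("ok", list(parse_fame_notation("C16:0", 60.4),
                            parse_fame_notation("C18:0", 40))),
    "fame_profile")
})

test_that("fixture reader yields the detected species only, ND omitted", {
  profiles <- table2_profiles()
  expect_named(profiles, c("PW", "BG-11"))
  expect_equal(nrow(profiles$PW$species), 9)
  expect_equal(nrow(profiles[["BG-11"]]$species), 9)
  # ND must not appear as a zero-weight species
  expect_false(any(profiles$PW$species$weight_percent == 0))
  expect_false("C21:0" %in% profiles$PW$species$notation)   # ND in PW
  expect_true("C21:0" %in% profiles[["BG-11"]]$species$notation)
})

test_that("CSV writer round-trips the fixture", {
  profiles <- table2_profiles()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_fame_csv(profiles, tmp)
  back <- read_fame_csv(tmp)
  expect_equal(names(back), names(profiles))
  for (sid in names(profiles)) {
    expect_equal(back[[sid]]$species$notation,
                 profiles[[sid]]$species$notation)
    expect_equal(back[[sid]]$species$weight_percent,
                 profiles[[sid]]$species$weight_percent)
  }
})

test_that("reader errors carry row/column context", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,S1", "C16:0,abc"), tmp)
  expect_error(read_fame_csv(tmp), "row 1, column 'S1'",
               class = "famefuel_io_error")
  writeLines(c("species,S1", "C16:0,10", "C16:0,20"), tmp)
  expect_error(read_fame_csv(tmp), "duplicate",
               class = "famefuel_io_error")
  writeLines(c("notation,S1", "C16:0,10"), tmp)
  expect_error(read_fame_csv(tmp), class = "famefuel_io_error")
})

test_that("JSON export writes one record per profile", {
  profiles <- table2_profiles()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_fame_json(profiles, tmp)
  back <- jsonlite::read_json(tmp)
  expect_named(back, c("PW", "BG-11"))
  expect_equal(length(back$PW$species), 9)
})
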