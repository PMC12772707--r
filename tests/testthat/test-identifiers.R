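# Independent checksum oracle: ISO 7064 mod 11-2 in its polynomial form,
# check = (12 - sum(d_i * 2^(n-i+1)) mod 11) mod 11 over the 15 base digits,
# computed with explicit modular exponentiation -- a different formulation
# from the package's recurrence.
oracle_mod11_2 <- function(digits15) {
  d <- as.integer(strsplit(digits15, "")[[1L]])
  n <- length(d)
  powmod <- function(e) {
    r <- 1L
    for (i in seq_len(e)) r <- (r * 2L) %% 11L
    r
  }
  total <- 0L
  for (i in seq_len(n)) {
    total <- (total + d[[i]] * powmod(n - i + 1L)) %% 11L
  }
  r <- (12L - total) %% 11L
  if (r == 10L) "X" else as.character(r)
}

test_that("mod 11-2 check character matches the polynomial oracle over random digits", {
  digs <- c("000000021825009", "123456789012345", "999999999999999",
            "000000000000000", "402893712046158", "070918273645501")
  for (d in digs) {
    expect_identical(iso7064_mod11_2_check(d), oracle_mod11_2(d), info = d)
  }
})

test_that("known ORCID validates; altering its check digit invalidates it", {
  good <- validate_identifier("ORCID", "0000-0002-1825-0097")
  expect_true(good$valid)
  expect_identical(good$normalized, "0000-0002-1825-0097")
  expect_false(validate_identifier("ORCID", "0000-0002-1825-0090")$valid)
  # unhyphenated input normalizes to hyphenated canonical form
  expect_identical(validate_identifier("ORCID", "0000000218250097")$normalized,
                   "0000-0002-1825-0097")
})

test_that("ISNI shares the checksum but normalizes compact", {
  expect_true(validate_identifier("ISNI", "0000 0001 2146 438X")$valid)
  expect_identical(validate_identifier("ISNI", "0000 0001 2146 438X")$normalized,
                   "000000012146438X")
  expect_false(validate_identifier("ISNI", "0000 0001 2146 4381")$valid)
})

test_that("scheme-specific syntax checks accept valid and reject malformed forms", {
  expect_true(validate_identifier("DOI", "10.1234/abcd")$valid)
  expect_false(validate_identifier("DOI", "11.1234/abcd")$valid)
  expect_false(validate_identifier("DOI", "10.1234/")$valid)
  expect_true(validate_identifier("ROR", "02twcfp32")$valid)
  expect_identical(validate_identifier("ROR", "https://ror.org/02twcfp32")$normalized,
                   "02twcfp32")
  expect_false(validate_identifier("ROR", "02twcfp3l")$valid)  # 'l' excluded
  expect_true(validate_identifier("RRID", "RRID:AB_90755")$valid)
  expect_false(validate_identifier("RRID", "AB_90755")$valid)
  expect_true(validate_identifier("PMID", "31974917")$valid)
  expect_false(validate_identifier("PMID", "PMC123")$valid)
  expect_true(validate_identifier("arXiv", "2104.01234v2")$valid)
  expect_true(validate_identifier("arXiv", "q-bio.NC/0309026")$valid)
  expect_true(validate_identifier("ISBN", "978-3-16-148410-0")$valid)
  expect_true(validate_identifier("GRDI", "grid.21107.35")$valid)
  expect_true(validate_identifier("GRID", "grid.21107.35")$valid)
  expect_true(validate_identifier("Other", "anything-goes")$valid)
  expect_false(validate_identifier("Other", "  ")$valid)
})

test_that("unknown schemes are configuration errors, not findings", {
  expect_error(validate_identifier("FOO", "x"), "unknown identifier scheme")
})

test_that("generated contributors carry ORCIDs the oracle accepts", {
  b <- small_bundle(17)
  pid <- names(b$entities$Project)
  for (ct in b$entities$Project[[pid]]$fields$Contributor) {
    orcid <- ct$fields$NameIdentifier
    compact <- gsub("-", "", orcid)
    expect_identical(substr(compact, 16L, 16L),
                     oracle_mod11_2(substr(compact, 1L, 15L)))
  }
})
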