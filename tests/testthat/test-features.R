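scheme5 <- type_code_scheme(c("T1", "T2", "T3", "T4", "T5"))

test_that("load_dictionary reads TSV entries and resolves type conflicts by priority", {
  f <- withr::local_tempfile()
  writeLines(c("ab\tT1", "cde\tT2", "fg\tT3"), f)
  d <- load_dictionary(f)
  expect_length(d, 3L)
  expect_equal(unname(d$entries["cde"]), "T2")

  writeLines(c("ab\tT2", "ab\tT1"), f)
  expect_warning(d2 <- load_dictionary(f, type_order = c("T1", "T2")),
                 "several types")
  expect_length(d2, 1L)
  expect_equal(unname(d2$entries["ab"]), "T1")   # higher priority wins

  writeLines(character(0), f)
  expect_length(load_dictionary(f), 0L)

  writeLines("ab\tMystery", f)
  expect_error(load_dictionary(f, type_order = c("T1", "T2")), "unknown type")
})

test_that("type codes are distinct non-zero 3-bit tuples; published tables load", {
  expect_length(scheme5$codes, 5L)
  keys <- vapply(scheme5$codes, paste, character(1), collapse = "")
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(keys != "000"))
  expect_equal(scheme5$none_code, c(0L, 0L, 0L))

  s17 <- builtin_scheme("ccks2017")
  expect_equal(s17$codes$disease, c(0L, 0L, 1L))
  expect_equal(s17$codes$treatment, c(1L, 0L, 1L))
  s18 <- builtin_scheme("ccks2018")
  expect_equal(s18$codes$drug, c(0L, 0L, 1L))
  expect_equal(s18$codes$operation, c(1L, 0L, 1L))

  expect_error(type_code_scheme(paste0("T", 1:8)), "at most 7")
  expect_error(type_code_scheme(c("A", "B"), list(c(0, 0, 0), c(0, 1, 0))),
               "non-zero")
})

test_that("fragments_at enumerates ten windows in fixed order with boundary absences", {
  chars <- strsplit("abcdefghijkl", "")[[1L]]   # length 12
  mid <- fragments_at(chars, 7)
  expect_length(mid, 10L)
  expect_false(anyNA(mid))
  expect_equal(nchar(mid), rep(2:6, each = 2))
  expect_equal(mid[1L], "fg")   # 2-gram left
  expect_equal(mid[2L], "gh")   # 2-gram right
  expect_equal(mid[9L], "bcdefg")
  expect_equal(mid[10L], "ghijkl")
  # every fragment contains position i
  expect_true(all(vapply(mid, function(f) grepl("g", f), logical(1))))

  expect_true(all(is.na(fragments_at("a", 1))))

  first <- fragments_at(chars, 1)
  expect_true(all(is.na(first[c(1, 3, 5, 7, 9)])))    # left windows absent
  expect_false(anyNA(first[c(2, 4, 6, 8, 10)]))       # right windows present

  expect_error(fragments_at(chars, 0), "out of range")
  expect_error(fragments_at(chars, 13), "out of range")
})

test_that("encode_position emits the matched fragment's 3-bit code in its slot", {
  chars <- strsplit("xxabyy", "")[[1L]]
  dict <- entity_dictionary("ab", "T1", type_order = names(scheme5$codes))
  # "ab" spans positions 3:4; at position 4 it is the 2-gram-left fragment
  v <- encode_position(chars, 4, dict, scheme5)
  expect_equal(v[1:3], c(0L, 0L, 1L))   # slot 1 = 2-gram left, T1 code
  expect_equal(sum(v), 1L)
  # at position 3 it is the 2-gram-right fragment (slot 2 -> dims 4:6)
  v3 <- encode_position(chars, 3, dict, scheme5)
  expect_equal(v3[4:6], c(0L, 0L, 1L))

  empty <- entity_dictionary(type_order = "T1")
  expect_equal(encode_position(chars, 3, empty, scheme5), integer(30))
})

test_that("encode_position matches the brute-force window enumerator", {
  set.seed(23)
  for (rep in 1:200) {
    n <- sample(1:14, 1L)
    chars <- rand_chars(n)
    dict <- rand_dict_for(chars, scheme5)
    i <- sample.int(n, 1L)
    expect_identical(encode_position(chars, i, dict, scheme5),
                     brute_encode_position(chars, i, dict, scheme5))
  }
})

test_that("encode_sentence_dict equals the positionwise encoding row by row", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:15, 1L)
    chars <- rand_chars(n)
    dict <- rand_dict_for(chars, scheme5)
    m <- encode_sentence_dict(chars, dict, scheme5)
    expect_equal(dim(m), c(n, 30L))
    for (i in seq_len(n))
      expect_identical(unname(m[i, ]), encode_position(chars, i, dict, scheme5))
  }
  expect_error(encode_sentence_dict(character(0), entity_dictionary(), scheme5),
               "empty")
})

test_that("dictionary vectors are 30-bit binary with at most ten active slots", {
  set.seed(37)
  for (rep in 1:50) {
    chars <- rand_chars(sample(1:12, 1L))
    dict <- rand_dict_for(chars, scheme5)
    i <- sample.int(length(chars), 1L)
    v <- encode_position(chars, i, dict, scheme5)
    expect_length(v, 30L)
    expect_true(all(v %in% c(0L, 1L)))
    active <- sum(vapply(1:10, function(s) any(v[(3 * s - 2):(3 * s)] == 1L),
                         logical(1)))
    expect_lte(active, 10L)
  }
})

test_that("growing the dictionary never clears a previously set slot", {
  set.seed(41)
  for (rep in 1:20) {
    chars <- rand_chars(10L)
    small <- rand_dict_for(chars, scheme5, n_entries = 2L)
    extra_frag <- fragments_at(chars, 5L)
    extra_frag <- extra_frag[!is.na(extra_frag)][1L]
    surfaces <- unique(c(names(small$entries), extra_frag))
    big <- entity_dictionary(
      surfaces,
      c(unname(small$entries),
        rep("T5", length(surfaces) - length(small$entries))),
      type_order = small$type_order)
    for (i in seq_along(chars)) {
      v1 <- encode_position(chars, i, small, scheme5)
      v2 <- encode_position(chars, i, big, scheme5)
      slots1 <- vapply(1:10, function(s) any(v1[(3 * s - 2):(3 * s)] == 1L),
                       logical(1))
      slots2 <- vapply(1:10, function(s) any(v2[(3 * s - 2):(3 * s)] == 1L),
                       logical(1))
      expect_true(all(slots2[slots1]))
    }
  }
})

test_that("encoding is translation-equivariant away from boundaries", {
  set.seed(43)
  chars <- rand_chars(12L)
  dict <- rand_dict_for(chars, scheme5)
  k <- 6L
  prefix <- rep("#", k)      # '#' matches nothing in the dictionary
  shifted <- c(prefix, chars)
  m0 <- encode_sentence_dict(chars, dict, scheme5)
  m1 <- encode_sentence_dict(shifted, dict, scheme5)
  # interior rows (at least 5 characters from either end of the original)
  for (i in 6:(length(chars) - 5L))
    expect_identical(m1[i + k, ], m0[i, ])
})

test_that("radical lookup is total with an unknown fallback", {
  tab <- radical_table(c("肝", "腺", "腹", "疼"),
                       c("meat", "meat", "meat", "sick"))
  expect_equal(radical_of("肝", tab), radical_of("腹", tab))
  expect_gt(radical_of("疼", tab), 0L)
  expect_equal(radical_of("3", tab), tab$unk_radical)
  # fuzz: arbitrary code points never error
  set.seed(47)
  for (cp in sample(c(65:1000, 0x4E00:0x4FFF), 50))
    expect_true(radical_of(intToUtf8(cp), tab) >= 0L)
  # contiguous 0-based id space
  ids <- sort(unique(c(tab$unk_radical, unname(tab$mapping))))
  expect_true(all(diff(ids) == 1L) && ids[1L] == 0L)
})

test_that("load_radicals round-trips a TSV table", {
  f <- withr::local_tempfile()
  writeLines(c("肝\tmeat", "疼\tsick"), f)
  tab <- load_radicals(f)
  expect_equal(length(tab$mapping), 2L)
  expect_gt(radical_of("肝", tab), 0L)
  writeLines("one\tcolumn\textra", f)
  expect_error(load_radicals(f), "2 columns")
})

test_that("init_embedding is bounded, reproducible, and has the uniform's moments", {
  dim <- 25L
  e <- init_embedding(400L, dim, rng_seed = 99L)
  bound <- sqrt(3 / dim)
  expect_true(all(e >= -bound & e <= bound))
  expect_identical(e, init_embedding(400L, dim, rng_seed = 99L))
  # mean 0, variance 1/dim within 3 standard errors
  n <- length(e)
  se_mean <- sqrt(1 / dim) / sqrt(n)
  expect_lt(abs(mean(e)), 3 * se_mean)
  expect_lt(abs(stats::var(as.vector(e)) - 1 / dim),
            3 * sqrt(2 / (n - 1)) / dim)
})

test_that("assemble_input concatenates embedding, radical and dictionary blocks", {
  E <- init_embedding(10L, 100L, 1L)
  R <- init_embedding(4L, 50L, 2L)
  dict_feats <- matrix(0L, 3L, 30L); dict_feats[2L, 5L] <- 1L
  X <- assemble_input(c(1L, 3L, 7L), c(0L, 2L, 1L), dict_feats, E, R)
  expect_equal(dim(X), c(3L, 180L))
  expect_equal(X[2L, 1:100], E[3L, ])
  expect_equal(X[2L, 101:150], R[3L, ])
  expect_equal(X[2L, 151:180], as.numeric(dict_feats[2L, ]))
  # zero embeddings leave exactly the dictionary bits
  X0 <- assemble_input(c(1L, 2L, 1L), c(0L, 0L, 0L), dict_feats, E * 0, R * 0)
  expect_equal(X0[2L, ], c(rep(0, 150), as.numeric(dict_feats[2L, ])))
  expect_error(assemble_input(1:2, 0L, dict_feats, E, R), "align")
})
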