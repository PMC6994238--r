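test_that("signatures compile token by token and match constructed strings", {
  m <- compile_signature("[FHY]xWxxKxx[FHY]")
  expect_equal(length(m$tokens), 9L)
  expect_equal(nrow(motif_match(m, "FAWGGKCCY")), 1L)

  wp <- compile_signature("WPxxxxxW")
  expect_equal(nrow(motif_match(wp, "WPACDEFW")), 1L)   # 5 wildcards
  expect_equal(nrow(motif_match(wp, "WPACDEW")), 0L)    # only 4
  # matching is case-insensitive over sequences
  expect_equal(nrow(motif_match(wp, "wpacdefw")), 1L)
})

test_that("reverse compilation reverses the token list, not the residues", {
  rv <- compile_signature("WPxxxxxW", "reverse")
  expect_equal(rv$regex$reverse, "W.....PW")
  # token reversal, so a class stays a class
  rv2 <- compile_signature("[FHY]xW", "reverse")
  expect_equal(rv2$regex$reverse, "W.[FHY]")
})

test_that("signature parse errors carry positions", {
  expect_error(compile_signature("[FHY"), "unbalanced bracket")
  expect_error(compile_signature("W[]W"), "empty class")
  expect_error(compile_signature("W?W"), "illegal character '\\?' at position 2")
  expect_error(compile_signature("[F1]"), "illegal character '1'")
})

test_that("overlapping matches are all reported", {
  m <- compile_signature("AxA")
  h <- motif_match(m, "AAAAA")
  expect_equal(h$start, c(0L, 1L, 2L))
  expect_equal(h$end - h$start, rep(3L, 3))
})

test_that("hit spans index the sequence correctly (0-based half-open)", {
  prot <- proteome("p1", "CCCWPACDEFWCCC")
  h <- search_proteome(prot, "WPxxxxxW")
  expect_equal(h$start, 3L)
  expect_equal(h$end, 11L)
  expect_equal(h$matched_seq, substr(prot$sequence, h$start + 1L, h$end))
})

test_that("the length window gates scanning inclusively on both bounds", {
  sim <- simulate_proteome_with_motifs(
    n_proteins = 3, lengths = c(100L, 230L, 260L),
    signature = "[FHY]xWxxKxx[FHY]", n_with_motif = 3, motif_hosts = 1:3,
    seed = 11
  )
  h <- search_proteome(sim$proteome, "[FHY]xWxxKxx[FHY]",
                       min_len = 220, max_len = 280)
  expect_setequal(attr(h, "proteins"), sim$proteome$id[2:3])
  # a perfect match in a 100-residue protein is invisible to a 128-147 window
  h2 <- search_proteome(sim$proteome, "[FHY]xWxxKxx[FHY]",
                        min_len = 128, max_len = 147)
  expect_equal(nrow(h2), 0L)
  # disabling the filter restores all three
  h3 <- search_proteome(sim$proteome, "[FHY]xWxxKxx[FHY]",
                        min_len = 220, max_len = 280,
                        apply_length_filter = FALSE)
  expect_setequal(attr(h3, "proteins"), sim$proteome$id)
  # inclusivity at the exact bounds
  h4 <- search_proteome(sim$proteome, "[FHY]xWxxKxx[FHY]",
                        min_len = 230, max_len = 260)
  expect_setequal(attr(h4, "proteins"), sim$proteome$id[2:3])
})

test_that("a reverse-planted pattern is found only in 'both'/'reverse' mode", {
  sim <- simulate_proteome_with_motifs(
    n_proteins = 2, lengths = c(150L, 150L), signature = "WPxxxxKW",
    n_with_motif = 1, motif_hosts = 2L, plant_direction = "reverse",
    seed = 13
  )
  fwd <- search_proteome(sim$proteome, "WPxxxxKW", direction = "forward")
  expect_equal(nrow(fwd), 0L)
  both <- search_proteome(sim$proteome, "WPxxxxKW", direction = "both")
  expect_equal(nrow(both), 1L)
  expect_equal(both$direction, "reverse")
  expect_equal(both$start, sim$truth$start)
})

test_that("matcher equals the brute-force oracle on random proteomes", {
  set.seed(303)
  sigs <- c("WPxxxxxW", "[FHY]xWxxKxx[FHY]", "KxK", "[ACD]x[WY]P")
  for (rep in 1:40) {
    prot <- random_proteome(sample(2:6, 1), c(20L, 120L))
    sig <- sample(sigs, 1)
    dirn <- sample(c("forward", "reverse", "both"), 1)
    got <- search_proteome(prot, sig, direction = dirn)
    want <- oracle_search(prot, sig, direction = dirn)
    expect_equal(hit_key(got), hit_key(want))
  }
})

test_that("window monotonicity: widening never removes hits", {
  sim <- simulate_proteome_with_motifs(
    n_proteins = 8, length_range = c(100L, 300L), signature = "KxKxW",
    n_with_motif = 5, seed = 17
  )
  narrow <- search_proteome(sim$proteome, "KxKxW", 150, 250)
  wide <- search_proteome(sim$proteome, "KxKxW", 100, 300)
  key_n <- do.call(paste, hit_key(narrow))
  key_w <- do.call(paste, hit_key(wide))
  expect_true(all(key_n %in% key_w))
})

test_that("a literal-only signature reduces to exact substring search", {
  prot <- random_proteome(5, c(50L, 100L))
  got <- search_proteome(prot, "WKW")
  for (i in seq_len(nrow(prot))) {
    m <- gregexpr("WKW", prot$sequence[i], fixed = TRUE)[[1]]
    want <- if (m[1] == -1L) integer(0) else as.integer(m) - 1L
    # fixed = TRUE misses overlaps; WKW cannot overlap itself except WKWKW
    got_i <- got$start[got$protein_id == prot$id[i]]
    expect_true(all(want %in% got_i))
  }
})

test_that("uppercase X in a signature is a literal, lowercase x a wildcard", {
  m_lit <- compile_signature("WXW")
  expect_equal(nrow(motif_match(m_lit, "WAW")), 0L)
  expect_equal(nrow(motif_match(m_lit, "WXW")), 1L)
  m_wild <- compile_signature("WxW")
  expect_equal(nrow(motif_match(m_wild, "WAW")), 1L)
})
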