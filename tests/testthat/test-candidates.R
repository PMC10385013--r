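test_that("the three-drug example anonymizes into the three expected rows", {
  s <- aminoglutethimide_sentence()
  cands <- generate_candidates(s)
  expect_length(cands, 3)
  expected <- c(
    "aminoglutethimide drug1 decreases the effect of coumarin drug2 and warfarin drugn",
    "aminoglutethimide drug1 decreases the effect of coumarin drugn and warfarin drug2",
    "aminoglutethimide drugn decreases the effect of coumarin drug1 and warfarin drug2")
  expect_setequal(tolower(vapply(cands, `[[`, "", "anon_text")), expected)
  for (cc in cands) {
    expect_lt(cc$p1, cc$p2)
    expect_identical(cc$tokens[cc$p1], "DRUG1")
    expect_identical(cc$tokens[cc$p2], "DRUG2")
    expect_identical(cc$dist_e1[cc$p1], 0L)
    expect_identical(cc$dist_e2[cc$p2], 0L)
  }
  # the replace style implements the prose variant
  crep <- generate_candidates(s, anonymization = "replace")
  expect_identical(tolower(crep[[1]]$anon_text),
                   "drug1 decreases the effect of drug2 and drugn")
})

test_that("candidate counts follow the pair-enumeration law", {
  # 1 entity -> 0 instances
  s1 <- token_sentence(c("Adrug", "acts", "alone"), list(1L))
  expect_length(generate_candidates(s1), 0)
  # exhaustive check against brute-force enumeration for n up to 12
  for (n in 2:12) {
    toks <- as.vector(rbind(paste0("Drug", letters[seq_len(n)]), "then"))
    s <- token_sentence(toks, as.list(seq(1L, by = 2L, length.out = n)))
    cands <- generate_candidates(s)
    expect_length(cands, n * (n - 1) / 2)
    got <- vapply(cands, function(x) paste(x$e1_id, x$e2_id), "")
    brute <- character(0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      brute <- c(brute, paste(s$entities[[i]]$id, s$entities[[j]]$id))
    expect_setequal(got, brute)
  }
})

test_that("labels come from gold pairs and default to negative", {
  s <- aminoglutethimide_sentence(with_pairs = TRUE)
  cands <- generate_candidates(s)
  labs <- vapply(cands, `[[`, "", "label")
  ids <- vapply(cands, function(x) paste(x$e1_id, x$e2_id), "")
  expect_identical(labs[ids == "s0.e0 s0.e1"], "effect")
  expect_identical(labs[ids == "s0.e1 s0.e2"], "negative")
})

test_that("anonymization is invertible on target-pair instances", {
  s <- aminoglutethimide_sentence()
  orig <- ddi_tokenize(s$text)
  for (cc in generate_candidates(s)) {
    # tag style: dropping the role symbols recovers the original token sequence
    expect_identical(cc$tokens[!cc$tokens %in% c("DRUG1", "DRUG2", "DRUGN")],
                     orig)
  }
  for (cc in generate_candidates(s, anonymization = "replace")) {
    # replace style: substituting the stored surfaces back recovers it
    toks <- cc$tokens
    toks[cc$p1] <- cc$e1_surface
    toks[cc$p2] <- cc$e2_surface
    others <- which(toks == "DRUGN")
    other_surfaces <- setdiff(vapply(s$entities, `[[`, "", "surface"),
                              c(cc$e1_surface, cc$e2_surface))
    toks[others] <- other_surfaces
    expect_identical(toks, orig)
  }
})

test_that("same-drug rule flags identical and synonym surfaces", {
  s <- token_sentence(c("Samedrug", "was", "compared", "with", "Samedrug"),
                      list(1L, 5L))
  cands <- filter_negatives(generate_candidates(s))
  expect_true(cands[[1]]$filtered)
  expect_identical(cands[[1]]$filter_reason, "same_drug")
  # synonym table extends the rule
  s2 <- token_sentence(c("Onedrug", "was", "compared", "with", "Otherdrug"),
                       list(1L, 5L))
  plain <- filter_negatives(generate_candidates(s2))
  expect_false(plain[[1]]$filtered)
  syn <- filter_negatives(generate_candidates(s2),
                          synonyms = list(c("onedrug", "otherdrug")))
  expect_identical(syn[[1]]$filter_reason, "same_drug")
})

test_that("coordination rule flags pure comma/conjunction lists only", {
  s <- ddi_sentence("co0",
    "aminoglycosides, tetracyclines, bacitracin, polymyxins were given",
    entities = list(
      entity_mention("co0.e0", list(c(0L, 14L)), "group", "aminoglycosides"),
      entity_mention("co0.e1", list(c(17L, 29L)), "group", "tetracyclines"),
      entity_mention("co0.e2", list(c(32L, 41L)), "drug", "bacitracin"),
      entity_mention("co0.e3", list(c(44L, 53L)), "drug", "polymyxins")))
  cands <- filter_negatives(generate_candidates(s))
  ids <- vapply(cands, function(x) paste(x$e1_id, x$e2_id), "")
  reasons <- vapply(cands, `[[`, "", "filter_reason")
  # independent hand check: between every pair only commas and drug mentions
  expect_true(all(reasons == "coordination"))
  # a verb between the anchors blocks the rule
  s2 <- aminoglutethimide_sentence()
  c2 <- filter_negatives(generate_candidates(s2))
  ids2 <- vapply(c2, function(x) paste(x$e1_id, x$e2_id), "")
  expect_identical(vapply(c2, `[[`, "", "filter_reason")[ids2 == "s0.e0 s0.e1"],
                   "none")
  # flagging is idempotent and never alters labels
  twice <- filter_negatives(c2)
  expect_identical(vapply(twice, `[[`, "", "filter_reason"),
                   vapply(c2, `[[`, "", "filter_reason"))
  expect_identical(vapply(twice, `[[`, "", "label"),
                   vapply(c2, `[[`, "", "label"))
})

test_that("relative distances follow the definition and clip at max_dist", {
  s <- token_sentence(c("Adrug", "decreases", "the", "effect", "of", "Bdrug"),
                      list(1L, 6L))
  cc <- generate_candidates(s, anonymization = "replace")[[1]]
  expect_identical(cc$dist_e1, 0:5)
  expect_identical(cc$dist_e2, -5:0)
  enc <- encode_positions(cc, max_dist = 3L)
  expect_identical(enc$dist_e1, c(0L, 1L, 2L, 3L, 3L, 3L))
  expect_identical(enc$dist_e2, c(-3L, -3L, -3L, -2L, -1L, 0L))
  # long sentence saturates at +/- 60
  toks <- c("Adrug", rep("w", 150L), "Bdrug", rep("v", 47L))
  sl <- token_sentence(toks, list(1L, 152L))
  cl <- encode_positions(generate_candidates(sl, "replace")[[1]], 60L)
  expect_true(all(abs(cl$dist_e1) <= 60L))
  expect_true(all(abs(cl$dist_e2) <= 60L))
  # distances are monotone non-decreasing in token index
  expect_true(all(diff(cl$dist_e1) >= 0L))
})

test_that("padding and anchor-preserving truncation work", {
  s <- token_sentence(c("Adrug", "inhibits", "Bdrug"), list(1L, 3L))
  cc <- encode_positions(generate_candidates(s, "replace")[[1]], 60L)
  padded <- pad_or_truncate(cc, 150L)
  expect_length(padded$tokens, 150L)
  expect_identical(sum(padded$pad_mask), 147L)
  expect_identical(pad_or_truncate(padded, 150L)$tokens, padded$tokens)

  # 200-token instance, anchors near 5 and 120: hand windowing rule says the
  # window is centred on the anchor span and clamped to [1, 51]
  toks <- c(rep("w", 200L))
  toks[5] <- "Adrug"; toks[120] <- "Bdrug"
  sl <- token_sentence(toks, list(5L, 120L))
  cl <- encode_positions(generate_candidates(sl, "replace")[[1]], 60L)
  tr <- pad_or_truncate(cl, 150L)
  expect_length(tr$tokens, 150L)
  expect_identical(tr$tokens[tr$p1], "DRUG1")
  expect_identical(tr$tokens[tr$p2], "DRUG2")
  expect_identical(tr$p2 - tr$p1, cl$p2 - cl$p1)
  # anchors that cannot fit together are an error
  toks2 <- rep("w", 400L); toks2[1] <- "Adrug"; toks2[400] <- "Bdrug"
  s2 <- token_sentence(toks2, list(1L, 400L))
  c2 <- generate_candidates(s2, "replace")[[1]]
  expect_error(pad_or_truncate(c2, 150L), "cannot fit")
})

test_that("marked encoder input has the documented structure", {
  s <- token_sentence(c("Adrug", "interacts", "with", "Bdrug"), list(1L, 4L),
                      pairs = list(drug_pair("tk0.p0", "tk0.e0", "tk0.e1",
                                             ddi = TRUE, itype = "int")))
  bi <- preprocess_for_bert(s, s$pairs[[1]], max_len = 16L)
  expect_identical(bi$tokens[1], "[CLS]")
  expect_identical(bi$tokens[seq_len(bi$length)][bi$length], "[SEP]")
  expect_identical(sum(bi$tokens == "[SEP]"), 1L)
  expect_identical(bi$tokens[2:4], c("$", "adrug", "$"))
  expect_identical(bi$tokens[7:9], c("#", "bdrug", "#"))
  expect_identical(bi$entity_pos_ids[3], 1L)
  expect_identical(bi$entity_pos_ids[8], 2L)
  expect_identical(sum(bi$entity_pos_ids == 1L), 1L)
  expect_identical(sum(bi$entity_pos_ids == 2L), 1L)
  # all context ids are 0, padding completes the length
  expect_true(all(bi$entity_pos_ids[-c(3L, 8L)] == 0L))
  expect_length(bi$tokens, 16L)
  expect_identical(bi$attention_mask, c(rep(1L, bi$length),
                                        rep(0L, 16L - bi$length)))
  expect_identical(bi$label, "int")
  # drug names are not anonymized on this path
  expect_false(any(grepl("drug1", bi$tokens, ignore.case = TRUE)))
})

test_that("candidate instances survive a JSON-lines round trip", {
  s <- aminoglutethimide_sentence(with_pairs = TRUE)
  cands <- lapply(filter_negatives(generate_candidates(s)), function(x)
    pad_or_truncate(encode_positions(x, 10L), 20L))
  tf <- withr::local_tempfile(fileext = ".jsonl")
  write_candidates_jsonl(cands, tf)
  back <- read_candidates_jsonl(tf)
  for (i in seq_along(cands)) {
    for (f in c("tokens", "p1", "p2", "dist_e1", "dist_e2", "label",
                "filtered", "filter_reason", "pad_mask"))
      expect_equal(back[[i]][[f]], cands[[i]][[f]],
                   ignore_attr = TRUE, label = f)
  }
})
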