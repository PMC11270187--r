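test_that("framework diffs exclude CDRs and are anti-symmetric", {
  pp <- parental_pair()
  gl <- graft(pp$light, germline_by_id("IGKV1-16"))
  d <- diff_framework(pp$light, gl)
  expect_true(all(d$region %in% c("FR1", "FR2", "FR3", "FR4")))
  # the canonical light-chain pair this workflow targets: K60->S and R66->G
  expect_true(all(c("60", "66") %in% d$position))
  expect_identical(d$parental_aa[d$position == "60"], "K")
  expect_identical(d$humanized_aa[d$position == "60"], "S")
  expect_identical(d$parental_aa[d$position == "66"], "R")
  expect_identical(d$humanized_aa[d$position == "66"], "G")
  # anti-symmetry
  rev <- diff_framework(gl, pp$light)
  expect_identical(rev$position, d$position)
  expect_identical(rev$parental_aa, d$humanized_aa)
  expect_identical(rev$humanized_aa, d$parental_aa)
  # identical chains: empty diff
  expect_identical(nrow(diff_framework(pp$light, pp$light)), 0L)
  # scheme mismatch errors
  expect_error(diff_framework(renumber(pp$light, "imgt"), gl),
               "scheme mismatch")
})

test_that("interface evidence yields direct-contact proposals for K60/R66", {
  pp <- parental_pair()
  px <- make_paratope_complex(pp$light, c("32", "60", "66"),
                              c("hbond", "salt_bridge", "hbond"))
  rep <- interface_bsa(px$model, n_points = 480,
                       regions = list(L = pp$light))
  gl <- graft(pp$light, germline_by_id("IGKV1-16"))
  pr <- propose_back_mutations(pp$light, gl, report = rep)
  p60 <- pr[pr$position == "60", ]
  p66 <- pr[pr$position == "66", ]
  expect_identical(nrow(p60), 1L)
  expect_identical(p60$evidence, "direct_contact")
  expect_identical(paste0(p60$humanized_aa, "60", p60$parental_aa), "S60K")
  expect_gte(p60$bsa, 10)
  expect_gte(p60$n_contacts, 1L)
  # position 66 contacts the antigen AND sits in the Vernier zone
  expect_identical(p66$evidence, "contact_and_vernier")
  expect_identical(paste0(p66$humanized_aa, "66", p66$parental_aa), "G66R")
  # ranking: contact_and_vernier first, then direct_contact, then vernier
  ev <- pr$evidence
  expect_identical(ev, ev[order(match(ev, c("contact_and_vernier",
                                            "direct_contact", "vernier")))])
})

test_that("Vernier positions propose without structural evidence; 71/78 couple", {
  pp <- parental_pair()
  gh <- graft(pp$heavy, germline_by_id("IGHV4-59"))
  d <- diff_framework(pp$heavy, gh)
  expect_true(all(c("71", "78") %in% d$position))
  pr <- propose_back_mutations(pp$heavy, gh)
  p71 <- pr[pr$position == "71", ]
  p78 <- pr[pr$position == "78", ]
  expect_identical(p71$evidence, "vernier")
  expect_identical(paste0(p71$humanized_aa, "71", p71$parental_aa), "V71K")
  expect_identical(paste0(p78$humanized_aa, "78", p78$parental_aa), "F78V")
  # with a parental structure in which 71 and 78 are spatially adjacent,
  # the steric pair is annotated
  pos <- pp$heavy$positions
  one2three <- abgraft:::AA_THREE_TO_ONE[1:20]
  coords <- lapply(seq_len(nrow(pos)), function(i) {
    base <- c((i %% 9) * 6, (i %/% 9) * 6, 0)
    data.frame(chain = "H", resno = i, ins = "",
               resid = names(one2three)[one2three == pos$aa[i]][1],
               elety = "CA", element = "C",
               x = base[1], y = base[2], z = base[3], o = 1)
  })
  atoms <- do.call(rbind, coords)
  i71 <- which(pos$label == "71"); i78 <- which(pos$label == "78")
  cb <- rbind(atoms[i71, ], atoms[i78, ])
  cb$elety <- "CB"
  cb$x <- c(100, 103); cb$y <- 0; cb$z <- 0   # 3 A apart, below couple_dist
  struct <- structure_model(rbind(atoms, cb))
  pr2 <- propose_back_mutations(pp$heavy, gh, structure = struct,
                                chain_id = "H")
  note <- pr2$partner_note[pr2$position == "78"]
  expect_match(note, "coupled with position 71")
})

test_that("proposals are a subset of framework diffs and threshold-monotone", {
  pp <- parental_pair()
  px <- make_paratope_complex(pp$light, c("60", "66"),
                              c("salt_bridge", "hbond"))
  rep <- interface_bsa(px$model, n_points = 480,
                       regions = list(L = pp$light))
  gl <- graft(pp$light, germline_by_id("IGKV1-39"))
  d <- diff_framework(pp$light, gl)
  thresholds <- c(1, 10, 30, 1e6)
  prev_direct <- Inf
  for (th in thresholds) {
    pr <- propose_back_mutations(pp$light, gl, report = rep,
                                 bsa_threshold = th)
    expect_true(all(pr$position %in% d$position), info = paste("th", th))
    n_direct <- sum(pr$evidence %in% c("direct_contact",
                                       "contact_and_vernier"))
    expect_lte(n_direct, prev_direct)
    prev_direct <- n_direct
  }
  # identical chains propose nothing even with a rich report
  expect_identical(nrow(propose_back_mutations(pp$light, pp$light,
                                               report = rep)), 0L)
})

test_that("applying all proposals then re-proposing yields an empty set", {
  pp <- parental_pair()
  gh <- graft(pp$heavy, germline_by_id("IGHV4-59"))
  gl <- graft(pp$light, germline_by_id("IGKV1-16"))
  px <- make_paratope_complex(pp$light, c("60", "66"),
                              c("salt_bridge", "hbond"))
  rep <- interface_bsa(px$model, n_points = 480,
                       regions = list(L = pp$light))
  cand <- build_panel(list(gh), list(gl), "C")[[1]]
  muts <- rbind(
    as_back_mutations(propose_back_mutations(pp$heavy, gh), "heavy"),
    as_back_mutations(propose_back_mutations(pp$light, gl, report = rep),
                      "light"))
  done <- apply_back_mutations(cand, muts)
  expect_identical(nrow(propose_back_mutations(pp$heavy, done$heavy)), 0L)
  expect_identical(nrow(propose_back_mutations(pp$light, done$light,
                                               report = rep)), 0L)
})

test_that("proposal reports serialize with threshold and provenance", {
  pp <- parental_pair()
  gh <- graft(pp$heavy, germline_by_id("IGHV4-59"))
  pr <- propose_back_mutations(pp$heavy, gh)
  expect_gt(nrow(pr), 0)
  path <- tempfile(fileext = ".json")
  write_proposals_json(pr, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$bsa_threshold, 10)
  expect_match(obj$vernier_provenance, "Foote")
  expect_identical(nrow(obj$proposals), nrow(pr))
})
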