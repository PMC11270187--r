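test_that("a chain's own framework ranks first with identity 1", {
  pp <- parental_pair()
  lib <- read_germline_library()
  self <- antibody_sequence("self", "heavy", pp$heavy$source$residues)
  rk <- rank_frameworks(pp$heavy, c(lib, list(self)))
  expect_identical(rk$gene_name[1], "self")
  expect_equal(rk$framework_identity[1], 1.0)
})

test_that("framework identities match a hand count on constructed entries", {
  # three kappa entries built from the template framework with 0, 4 and 20
  # framework substitutions; the kappa framework spans 80 positions, so the
  # expected identities are 80/80, 76/80 and 60/80
  ts <- template_sequence("kabat", "kappa")
  fr_idx <- which(!abgraft:::is_cdr(ts$tmpl$region) &
                    !(ts$tmpl$label %in% abgraft:::anchor_labels("kabat", "kappa")))
  expect_identical(sum(!abgraft:::is_cdr(ts$tmpl$region)), 80L)
  mutate_at <- function(aa, idx) {
    for (i in idx) aa[i] <- if (aa[i] == "A") "G" else "A"
    aa
  }
  set.seed(4)
  mk <- function(id, nmut) {
    aa <- mutate_at(ts$tmpl$aa, sample(fr_idx, nmut))
    antibody_sequence(id, "kappa", paste(aa, collapse = ""))
  }
  lib <- list(mk("g0", 0), mk("g4", 4), mk("g20", 20))
  parental <- number_sequence(template_chain("kabat", "kappa"), "kabat")
  rk <- rank_frameworks(parental, lib)
  expect_identical(rk$gene_name, c("g0", "g4", "g20"))
  expect_equal(rk$framework_identity, c(80, 76, 60) / 80)
})

test_that("the named human germlines are the top heavy-library hits", {
  pp <- parental_pair()
  lib <- read_germline_library()
  human <- Filter(function(e) !grepl("synthetic murine", e$source_tag), lib)
  rk <- rank_frameworks(pp$heavy, human, top_k = 3)
  expect_setequal(rk$gene_name, c("IGHV4-59", "IGHV2-26", "IGHV4-4"))
})

test_that("self-graft reproduces the parental sequence exactly", {
  pp <- parental_pair()
  for (nc in pp) {
    self <- antibody_sequence("self", nc$source$chain_class,
                              nc$source$residues)
    g <- graft(nc, self)
    expect_identical(g$source$residues, nc$source$residues)
  }
})

test_that("graft output = acceptor frameworks + parental CDRs", {
  pp <- parental_pair()
  acc <- germline_by_id("IGKV1-39")
  g <- graft(pp$light, acc)
  donor <- extract_regions(pp$light)
  out <- extract_regions(g)
  for (r in c("CDR1", "CDR2", "CDR3"))
    expect_identical(out[[r]], donor[[r]])
  acc_nc <- number_sequence(acc, "kabat")
  acc_regs <- extract_regions(number_sequence(antibody_sequence(
    "accfull", "kappa",
    paste0(acc$residues, substr(g$source$residues,
                                nchar(g$source$residues) - 9,
                                nchar(g$source$residues)))), "kabat"))
  for (r in c("FR1", "FR2"))
    expect_identical(out[[r]], acc_regs[[r]])
  # length identity: acceptor framework length + parental CDR lengths
  fr_len <- sum(nchar(unlist(out[c("FR1", "FR2", "FR3", "FR4")])))
  cdr_len <- sum(nchar(unlist(donor[c("CDR1", "CDR2", "CDR3")])))
  expect_identical(nchar(g$source$residues), fr_len + cdr_len)
})

test_that("graft idempotence: regrafting onto the same acceptor is a fixed point", {
  pp <- parental_pair()
  acc <- germline_by_id("IGHV2-26")
  g1 <- graft(pp$heavy, acc)
  g2 <- graft(g1, acc)
  expect_identical(g2$source$residues, g1$source$residues)
})

test_that("Kabat and IMGT grafts differ only where CDR definitions disagree", {
  p <- parental_antibody()
  acc <- germline_by_id("IGHV4-59")
  nk <- number_sequence(p$heavy, "kabat")
  ni <- number_sequence(p$heavy, "imgt")
  gk <- graft(nk, acc)
  gi <- graft(ni, acc)
  # CDR residues under each definition equal the parental CDRs
  expect_identical(extract_regions(gk)$CDR2, extract_regions(nk)$CDR2)
  expect_identical(extract_regions(gi)$CDR2, extract_regions(ni)$CDR2)
  # compare the two grafts in a common label space (Kabat)
  gik <- renumber(gi, "kabat")
  m <- merge(gk$positions[, c("label", "aa")], gik$positions[, c("label", "aa")],
             by = "label", suffixes = c("_k", "_i"))
  diff_labels <- m$label[m$aa_k != m$aa_i]
  # labels that are CDR under exactly one definition, read off the parental
  # chain numbered both ways (same residue order)
  one_scheme_cdr <- nk$positions$label[
    xor(abgraft:::is_cdr(nk$positions$region),
        abgraft:::is_cdr(ni$positions$region))]
  expect_true(all(diff_labels %in% one_scheme_cdr))
  expect_gt(length(diff_labels), 0)
})

test_that("panel construction is combinatorial, ordered and deterministic", {
  pp <- parental_pair()
  lib <- read_germline_library()
  heavy_accs <- Filter(function(e) e$chain_class == "heavy" &&
                         !grepl("synthetic murine", e$source_tag), lib)
  light_accs <- Filter(function(e) e$chain_class == "kappa" &&
                         !grepl("synthetic murine", e$source_tag), lib)
  hs <- lapply(heavy_accs, function(a) graft(pp$heavy, a))
  ls <- lapply(light_accs, function(a) graft(pp$light, a))
  panel <- build_panel(hs, ls, "V")
  expect_length(panel, 9L)
  expect_identical(names(panel)[1:4], c("VH1L1", "VH1L2", "VH1L3", "VH2L1"))
  panel2 <- build_panel(hs, ls, "V")
  expect_identical(names(panel2), names(panel))
  expect_identical(panel2[["VH3L2"]]$heavy$source$residues,
                   panel[["VH3L2"]]$heavy$source$residues)
  expect_length(build_panel(hs[1], ls[1], "S"), 1L)
  expect_error(build_panel(list(), ls), "non-empty")
})

test_that("back-mutations validate, apply and are ledgered", {
  pp <- parental_pair()
  gh <- graft(pp$heavy, germline_by_id("IGHV2-26"))
  gl <- graft(pp$light, germline_by_id("IGKV1-16"))
  cand <- build_panel(list(gh), list(gl), "V17like")[[1]]
  # the humanized light chain carries S60/G66 from the human germline
  expect_identical(cand$light$positions$aa[cand$light$positions$label == "60"],
                   "S")
  expect_identical(cand$light$positions$aa[cand$light$positions$label == "66"],
                   "G")
  muts <- rbind(back_mutation("light", "60", "S", "K"),
                back_mutation("light", "66", "G", "R"))
  v21 <- apply_back_mutations(cand, muts)
  expect_identical(v21$light$positions$aa[v21$light$positions$label == "60"],
                   "K")
  expect_identical(v21$light$positions$aa[v21$light$positions$label == "66"],
                   "R")
  expect_identical(nrow(v21$back_mutations), 2L)
  # an empty mutation list is a no-op
  expect_identical(apply_back_mutations(cand, abgraft:::empty_back_mutations()),
                   cand)
  # a stale precondition errors with position, expected and found residues
  expect_error(apply_back_mutations(v21, back_mutation("light", "60", "S", "K")),
               "60.*expected S.*found K")
})

test_that("every candidate framework residue is attributable to acceptor or ledger", {
  pp <- parental_pair()
  acc_h <- germline_by_id("IGHV4-59")
  acc_l <- germline_by_id("IGKV1-16")
  cand <- build_panel(list(graft(pp$heavy, acc_h)),
                      list(graft(pp$light, acc_l)), "V")[[1]]
  cand <- apply_back_mutations(cand, rbind(
    back_mutation("light", "60", "S", "K"),
    back_mutation("heavy", "71", "V", "K")))
  for (slot in c("heavy", "light")) {
    nc <- cand[[slot]]
    acc <- if (slot == "heavy") acc_h else acc_l
    acc_pos <- number_sequence(acc, "kabat")$positions
    ledger <- cand$back_mutations[cand$back_mutations$chain == slot, ]
    fr <- nc$positions[!abgraft:::is_cdr(nc$positions$region), ]
    for (i in seq_len(nrow(fr))) {
      lab <- fr$label[i]
      from_acc <- acc_pos$aa[acc_pos$label == lab]
      in_ledger <- lab %in% ledger$position
      attributable <- in_ledger ||
        (length(from_acc) == 1L && from_acc == fr$aa[i]) ||
        # FR4 tail comes from the bundled J consensus when absent in the V gene
        (length(from_acc) == 0L && fr$region[i] == "FR4")
      expect_true(attributable, info = paste(slot, lab))
    }
    if (nrow(ledger))
      for (i in seq_len(nrow(ledger)))
        expect_identical(
          nc$positions$aa[nc$positions$label == ledger$position[i]],
          ledger$to_aa[i])
  }
})

test_that("panels round-trip through FASTA with provenance headers", {
  pp <- parental_pair()
  gh <- graft(pp$heavy, germline_by_id("IGHV4-4"))
  gl <- graft(pp$light, germline_by_id("IGKV1-6"))
  panel <- build_panel(list(gh), list(gl), "R")
  path <- tempfile(fileext = ".fasta")
  write_panel_fasta(panel, path)
  back <- read_antibody_fasta(path)
  expect_length(back, 2L)
  expect_identical(back[[1]]$residues, gh$source$residues)
  expect_match(back[[1]]$source_tag, "acceptor=IGHV4-4")
})
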