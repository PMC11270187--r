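test_that("template sequences are numbered onto their own labels", {
  for (cls in c("heavy", "kappa", "lambda")) {
    for (scheme in c("kabat", "imgt")) {
      ts <- template_sequence(scheme, cls)
      nc <- number_sequence(antibody_sequence("t", cls, ts$seq), scheme)
      expect_identical(nc$positions$label, ts$tmpl$label,
                       info = paste(scheme, cls))
      expect_identical(nc$positions$region, ts$tmpl$region,
                       info = paste(scheme, cls))
    }
  }
  # IMGT heavy template: plain ascending numbers, no insertion codes
  ts <- template_sequence("imgt", "heavy")
  nc <- number_sequence(antibody_sequence("t", "heavy", ts$seq), "imgt")
  expect_true(all(nc$positions$ins == ""))
  expect_true(all(diff(nc$positions$number) >= 1))
  expect_true(all(nc$positions$number >= 1 & nc$positions$number <= 128))
})

test_that("degenerate sequences are rejected as unnumberable", {
  expect_error(antibody_sequence("e", "heavy", ""), "non-empty")
  expect_error(number_sequence(antibody_sequence("short", "heavy",
                                                 "QVQLVESGG"), "imgt"),
               "unnumberable")
  expect_error(number_sequence(
    antibody_sequence("long", "heavy",
                      paste(rep("A", 150), collapse = "")), "kabat"),
    "unnumberable")
})

test_that("a framework deletion skips exactly that label", {
  # expected labels derived by construction: remove one unambiguous
  # template residue, all other labels must be unchanged
  cases <- list(list(scheme = "imgt", cls = "heavy", drop_label = "12"),
                list(scheme = "kabat", cls = "kappa", drop_label = "18"),
                list(scheme = "imgt", cls = "kappa", drop_label = "70"))
  for (cs in cases) {
    ts <- template_sequence(cs$scheme, cs$cls)
    at <- which(ts$tmpl$label == cs$drop_label)
    mutseq <- paste(ts$tmpl$aa[-at], collapse = "")
    nc <- number_sequence(antibody_sequence("del", cs$cls, mutseq), cs$scheme)
    expect_identical(nc$positions$label, ts$tmpl$label[-at],
                     info = paste(cs$scheme, cs$cls, cs$drop_label))
  }
})

test_that("nonstandard residues at anchors fail loudly", {
  ts <- template_sequence("imgt", "heavy")
  q <- ts$tmpl$aa
  q[ts$tmpl$label == "23"] <- "X"
  expect_error(number_sequence(antibody_sequence("x", "heavy",
                                                 paste(q, collapse = "")),
                               "imgt"),
               "unnumberable.*anchor")
})

test_that("regions partition the sequence completely and in order", {
  pp <- parental_pair()
  for (nc in pp) {
    regs <- extract_regions(nc)
    expect_identical(paste(unlist(regs), collapse = ""), nc$source$residues)
    # regions contiguous and in canonical order
    runs <- rle(nc$positions$region)$values
    expect_identical(runs, c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3",
                             "FR4"))
  }
  # Kabat kappa LCDR2 spans 7 positions: the extracted string has length 7
  expect_identical(nchar(extract_regions(pp$light)$CDR2), 7L)
})

test_that("a chain truncated before FR4 errors naming the region", {
  pp <- parental_pair()
  full <- pp$heavy$source$residues
  upto_cdr3 <- substr(full, 1, nchar(full) - 11) # drop the 11-residue FR4
  nc <- number_sequence(antibody_sequence("tr", "heavy", upto_cdr3), "kabat")
  expect_error(extract_regions(nc), "region FR4 absent")
})

test_that("renumbering round-trips between schemes", {
  pp <- parental_pair("kabat")
  for (nc in pp) {
    back <- renumber(renumber(nc, "imgt"), "kabat")
    expect_identical(back$positions$label, nc$positions$label)
    expect_identical(back$positions$region, nc$positions$region)
  }
  # numbering is idempotent on the extracted sequence
  again <- number_sequence(pp$heavy$source, "kabat")
  expect_identical(again$positions, pp$heavy$positions)
})

test_that("conserved anchors carry their canonical residues in both schemes", {
  pp <- parental_pair("kabat")
  expect_identical(pp$heavy$positions$aa[pp$heavy$positions$label == "22"], "C")
  expect_identical(pp$heavy$positions$aa[pp$heavy$positions$label == "92"], "C")
  expect_identical(pp$heavy$positions$aa[pp$heavy$positions$label == "36"], "W")
  im <- renumber(pp$heavy, "imgt")
  expect_identical(im$positions$aa[im$positions$label == "23"], "C")
  expect_identical(im$positions$aa[im$positions$label == "104"], "C")
  expect_identical(im$positions$aa[im$positions$label == "118"], "W")
})

test_that("generated sequences are numbered in agreement with generator truth", {
  for (cls in c("heavy", "kappa")) {
    gen <- make_sequence_set(30, indel_rate = 0.1, mutation_rate = 0.03,
                             seed = 11, chain_class = cls, scheme = "kabat")
    for (k in seq_along(gen$sequences)) {
      nc <- number_sequence(gen$sequences[[k]], "kabat")
      expect_identical(nc$positions$label, gen$truth[[k]]$label,
                       info = paste(cls, k))
      expect_identical(nc$positions$region, gen$truth[[k]]$region,
                       info = paste(cls, k))
      # round-trip through the other scheme preserves labels
      back <- renumber(renumber(nc, "imgt"), "kabat")
      expect_identical(back$positions$label, nc$positions$label,
                       info = paste("roundtrip", cls, k))
    }
  }
})

test_that("numbered chains serialize to JSON with positions and regions", {
  pp <- parental_pair()
  path <- tempfile(fileext = ".json")
  write_numbered_json(pp$light, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(obj$scheme, "kabat")
  expect_identical(nrow(obj$positions), nrow(pp$light$positions))
  expect_true(all(c("label", "region", "aa") %in% names(obj$positions)))
})
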