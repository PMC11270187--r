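test_that("planted contacts are recovered with their planted types", {
  toy <- make_toy_interface(6)
  ct <- detect_contacts(toy$model)
  expect_identical(nrow(ct), 6L)
  expect_identical(ct$type, toy$truth$type)
  expect_equal(ct$distance, toy$truth$distance, tolerance = 1e-6)
  # single planted lysine-glutamate pair at 3.0 A is one salt bridge
  one <- make_toy_interface(1)
  ct1 <- detect_contacts(one$model)
  expect_identical(ct1$type, "salt_bridge")
  expect_identical(ct1$atom_a, "NZ")
})

test_that("well-separated chains yield no contacts and zero BSA", {
  toy <- make_toy_interface(0, separation = 30)
  expect_identical(nrow(detect_contacts(toy$model)), 0L)
  rep <- interface_bsa(toy$model, n_points = 240)
  expect_true(all(rep$per_residue$bsa == 0))
  expect_true(all(rep$totals == 0))
})

test_that("detection equals the brute-force all-pairs oracle", {
  # a mixed fixture: planted pairs of every type plus random nearby beads
  toy <- make_toy_interface(8)
  extra <- rbind(
    data.frame(chain = "A", resno = 50, ins = "", resid = "ARG",
               elety = "NH1", element = "N", x = 0, y = -8, z = 0, o = 1),
    data.frame(chain = "B", resno = 50, ins = "", resid = "ASP",
               elety = "OD1", element = "O", x = 3.2, y = -8, z = 0, o = 1),
    data.frame(chain = "B", resno = 51, ins = "", resid = "THR",
               elety = "OG1", element = "O", x = 2.8, y = -11, z = 0, o = 1))
  model <- structure_model(rbind(toy$model$atoms[, names(extra)], extra),
                           partition = toy$model$partition)
  expect_lte(nrow(model$atoms), 500L)
  got <- detect_contacts(model)
  want <- brute_force_contacts(model)
  key <- function(df) sort(paste(df$type, df$chain_a, df$resno_a, df$atom_a,
                                 df$chain_b, df$resno_b, df$atom_b))
  expect_identical(key(got), key(want))
})

test_that("contact precedence prefers salt bridge over hydrogen bond", {
  # Lys NZ vs Glu OE1 at 3.0 A satisfies both rules; must be typed salt_bridge
  atoms <- rbind(
    data.frame(chain = "A", resno = 1, ins = "", resid = "LYS", elety = "NZ",
               element = "N", x = 0, y = 0, z = 0, o = 1),
    data.frame(chain = "B", resno = 1, ins = "", resid = "GLU", elety = "OE1",
               element = "O", x = 3.0, y = 0, z = 0, o = 1))
  m <- structure_model(atoms, partition = list(A = "A", B = "B"))
  expect_identical(detect_contacts(m)$type, "salt_bridge")
  # widen nothing: same pair beyond every cutoff is no contact
  atoms$x[2] <- 8.0
  m2 <- structure_model(atoms, partition = list(A = "A", B = "B"))
  expect_identical(nrow(detect_contacts(m2)), 0L)
})

test_that("a symmetric homodimer buries equal area on both sides", {
  # the two protomers are related by central inversion, an exact symmetry
  # of the antipodal SASA point set, so totals must agree to numeric zero
  half <- random_ca_model(12, seed = 5, spread = 6)
  other <- half$atoms
  other$chain <- "B"
  other$x <- 14 - other$x   # inversion through (7, 3, 3): clouds ~2 A apart
  other$y <- 6 - other$y
  other$z <- 6 - other$z
  dimer <- structure_model(rbind(half$atoms, other),
                           partition = list(left = "A", right = "B"))
  rep <- interface_bsa(dimer, n_points = 960)
  expect_gt(rep$totals[["left"]], 0)
  expect_equal(rep$totals[["left"]], rep$totals[["right"]],
               tolerance = 1e-9)
})

test_that("per-residue BSA is side-alone minus complex with region fractions", {
  pp <- parental_pair()
  px <- make_paratope_complex(pp$light, c("32", "50", "60", "66"),
                              c("hbond", "hydrophobic", "salt_bridge",
                                "hbond"))
  rep <- interface_bsa(px$model, n_points = 480,
                       regions = list(L = pp$light))
  pr <- rep$per_residue
  # all burial sits on the planted residues
  ab <- pr[pr$side == "antibody", ]
  expect_setequal(ab$label[ab$bsa > 0], c("32", "50", "60", "66"))
  # side totals equal the sums of their residues, fractions sum to one
  expect_equal(sum(ab$bsa), rep$totals[["antibody"]])
  f <- rep$fraction_bsa_by_region_class$antibody
  expect_equal(sum(f), 1)
  expect_gt(f[["framework"]], 0) # K60/R66 burial is framework burial
  # manual check: BSA of K60 equals its isolated-side SASA loss
  alone <- compute_sasa(abgraft:::subset_model(px$model, "L"),
                        n_points = 480)$per_residue
  cx <- compute_sasa(px$model, n_points = 480)$per_residue
  i60 <- which(ab$label == "60")
  j <- which(alone$resno == ab$resno[i60])
  k <- which(cx$chain == "L" & cx$resno == ab$resno[i60])
  expect_equal(ab$bsa[i60], alone$sasa[j] - cx$sasa[k], tolerance = 1e-9)
})

test_that("interface reports serialize to JSON and TSV", {
  toy <- make_toy_interface(2)
  rep <- interface_bsa(toy$model, n_points = 240)
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
  write_interface_report(rep, jp)
  write_interface_report(rep, tp, format = "tsv")
  obj <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(obj$totals[["left"]], rep$totals[["left"]])
  expect_match(obj$bsa_convention, "side-alone minus complex")
  tab <- utils::read.delim(tp)
  expect_identical(nrow(tab), nrow(rep$per_residue))
})
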