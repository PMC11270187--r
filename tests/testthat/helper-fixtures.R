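# shared helpers for the test suite: template access, rigid motions, and a
# tiny random-structure builder

template_sequence <- function(scheme, chain_class) {
  tmpl <- abgraft:::numbering_template(scheme, chain_class)
  list(seq = paste(tmpl$aa, collapse = ""), tmpl = tmpl)
}

template_chain <- function(scheme, chain_class, id = "tmpl") {
  ts <- template_sequence(scheme, chain_class)
  antibody_sequence(id, chain_class, ts$seq)
}

rigid_move <- function(model, angles = c(0.4, -0.8, 1.1),
                       shift = c(3, -7, 2)) {
  rot1 <- function(th, i, j) {
    R <- diag(3)
    R[i, i] <- cos(th); R[j, j] <- cos(th)
    R[i, j] <- -sin(th); R[j, i] <- sin(th)
    R
  }
  R <- rot1(angles[1], 1, 2) %*% rot1(angles[2], 2, 3) %*% rot1(angles[3], 1, 3)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1] + shift[1]
  model$atoms$y <- xyz[, 2] + shift[2]
  model$atoms$z <- xyz[, 3] + shift[3]
  model
}

random_ca_model <- function(n, seed, chain = "A", spread = 8) {
  set.seed(seed)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(chain = chain, resno = i, ins = "", resid = "ALA",
               elety = "CA", element = "C",
               x = stats::runif(1, 0, spread),
               y = stats::runif(1, 0, spread),
               z = stats::runif(1, 0, spread), o = 1,
               stringsAsFactors = FALSE)))
  structure_model(atoms, model_id = paste0("rnd", seed))
}

parental_pair <- function(scheme = "kabat") {
  p <- parental_antibody()
  list(heavy = number_sequence(p$heavy, scheme),
       light = number_sequence(p$light, scheme))
}

germline_by_id <- function(id) {
  lib <- read_germline_library()
  lib[[which(vapply(lib, `[[`, "", "id") == id)]]
}
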