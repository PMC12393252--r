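# Independent oracles and shared fixtures for the test suite. Each oracle is
# a deliberately different route to the same quantity than the implementation
# under test.

# ---- nearest-neighbor hand-summing oracle -----------------------------------
# Frozen unified DNA/DNA parameters, written out literally and summed without
# reusing any package code path beyond basic string handling.
.oracle_nn <- list(
  dh = c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
         GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
         CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0),
  ds = c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
         TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
         GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
         CC = -19.9),
  init_dh = 0.2, init_ds = -5.7, termAT_dh = 2.2, termAT_ds = 6.9)

oracle_perfect_duplex_dg <- function(seq, temperature_C = 37, sodium_M = 0.3) {
  ch <- strsplit(seq, "")[[1]]
  stacks <- paste0(ch[-length(ch)], ch[-1])
  dh <- sum(.oracle_nn$dh[stacks]) + .oracle_nn$init_dh
  ds <- sum(.oracle_nn$ds[stacks]) + .oracle_nn$init_ds
  n_at <- sum(c(ch[1], ch[length(ch)]) %in% c("A", "T"))
  dh <- dh + n_at * .oracle_nn$termAT_dh
  ds <- ds + n_at * .oracle_nn$termAT_ds
  ds <- ds + 0.368 * length(stacks) * log(sodium_M)
  unname(dh - (temperature_C + 273.15) * ds / 1000)
}

# ---- Poisson-Binomial oracles -----------------------------------------------
# Exhaustive enumeration over all 2^N site outcomes.
oracle_pb_enumerate <- function(p) {
  n <- length(p)
  pmf <- numeric(n + 1)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    prob <- prod(ifelse(bits == 1, p, 1 - p))
    pmf[sum(bits) + 1] <- pmf[sum(bits) + 1] + prob
  }
  pmf
}

# Generating-function route: evaluate the product prod_s (1 - p_s + p_s z)
# at the (N+1)-th roots of unity and recover the coefficients by inverse
# DFT — a genuinely different expansion than iterated convolution.
oracle_pb_genfun <- function(p) {
  n <- length(p)
  z <- exp(2i * pi * (0:n) / (n + 1))
  g <- vapply(z, function(zz) prod(1 - p + p * zz), complex(1))
  Re(stats::fft(g)) / (n + 1)
}

# ---- brute-force Smith-Waterman oracle --------------------------------------
# Full local alignment of each probe's binding-site sequence against every
# transcript via Biostrings, same scoring and retention rule as find_hits().
oracle_brute_hits <- function(candidates, transcriptome, min_match = 15) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3,
                                                  baseOnly = TRUE)
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    q <- revcomp(candidates$sequence[i])
    for (t in seq_len(nrow(transcriptome))) {
      al <- Biostrings::pairwiseAlignment(
        q, transcriptome$sequence[t], type = "local",
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
      if (Biostrings::score(al) > 0 && Biostrings::nmatch(al) >= min_match) {
        sub <- Biostrings::subject(al)
        out[[length(out) + 1]] <- tibble::tibble(
          probe_id = candidates$probe_id[i],
          target_id = transcriptome$transcript_id[t],
          target_start = BiocGenerics::start(sub) - 1L,
          target_end = BiocGenerics::end(sub),
          matched_nt = Biostrings::nmatch(al),
          score = Biostrings::score(al))
      }
    }
  }
  dplyr::bind_rows(out)
}

hit_key <- function(h) {
  paste(h$probe_id, h$target_id, h$target_start, h$target_end,
        h$matched_nt, h$score)
}

# ---- equilibrium root-finding oracle ----------------------------------------
# Solves the full mass-balance system (free probes AND free sites as
# unknowns) with pracma::fsolve in nanomolar units.
oracle_equilibrium <- function(kds, probe_total_M, site_total_M) {
  probes <- names(probe_total_M)
  np <- length(probes)
  skey <- paste(site_total_M$target_id, site_total_M$site_id)
  ns <- length(skey)
  ka <- matrix(0, np, ns, dimnames = list(probes, skey))
  for (r in seq_len(nrow(kds$site))) {
    k <- paste(kds$site$target_id[r], kds$site$site_id[r])
    if (kds$site$probe_id[r] %in% probes && k %in% skey) {
      ka[kds$site$probe_id[r], k] <- 1 / kds$site$kd[r]
    }
  }
  kself <- setNames(rep(0, np), probes)
  if (nrow(kds$self)) {
    ok <- kds$self$probe_id %in% probes
    kself[kds$self$probe_id[ok]] <- 1 / kds$self$kd[ok]
  }
  kc <- matrix(0, np, np, dimnames = list(probes, probes))
  for (r in seq_len(nrow(kds$cross))) {
    i <- kds$cross$probe_i[r]; j <- kds$cross$probe_j[r]
    if (i %in% probes && j %in% probes) {
      kc[i, j] <- 1 / kds$cross$kd[r]
      kc[j, i] <- 1 / kds$cross$kd[r]
    }
  }
  alpha <- matrix(1, np, np); diag(alpha) <- 2
  stot <- site_total_M$total_M
  scale <- 1e9
  resid <- function(x) {
    p <- x[seq_len(np)] / scale
    t <- x[np + seq_len(ns)] / scale
    rp <- p + p * kself +
      as.vector((alpha * kc * outer(p, p)) %*% rep(1, np)) +
      as.vector(ka %*% t) * p - probe_total_M
    rt <- t + t * as.vector(crossprod(ka, p)) - stot
    c(rp, rt) * scale
  }
  # full-system Newton with pracma's numerical Jacobian and step halving
  x <- c(probe_total_M, stot) * scale
  for (it in 1:200) {
    fx <- resid(x)
    if (max(abs(fx)) <= 1e-12 * max(x)) break
    J <- pracma::jacobian(resid, x)
    step <- solve(J, fx)
    lambda <- 1
    while (any(x - lambda * step <= 0) && lambda > 1e-8) lambda <- lambda / 2
    x_new <- x - lambda * step
    while (max(abs(resid(x_new))) > max(abs(fx)) && lambda > 1e-8) {
      lambda <- lambda / 2
      x_new <- x - lambda * step
    }
    x <- x_new
  }
  list(probe_free = x[seq_len(np)] / scale,
       site_free = x[np + seq_len(ns)] / scale)
}

# ---- random equilibrium instances -------------------------------------------
empty_kd_tbl <- function() {
  tibble::tibble(probe_id = character(), target_id = character(),
                 site_id = character(), kd = numeric(), dg_min = numeric())
}

make_kds <- function(site = NULL, self = NULL, cross = NULL) {
  structure(list(
    site = site %||% empty_kd_tbl(),
    self = self %||% tibble::tibble(probe_id = character(), kd = numeric(),
                                    dg_min = numeric()),
    cross = cross %||% tibble::tibble(probe_i = character(),
                                      probe_j = character(),
                                      kd = numeric(), dg_min = numeric()),
    conditions = thermo_conditions()), class = "fish_kd")
}

random_instance <- function(seed, max_probes = 4, max_sites = 5) {
  set.seed(seed)
  np <- sample(1:max_probes, 1)
  ns <- sample(1:max_sites, 1)
  probes <- paste0("p", seq_len(np))
  sites <- tibble::tibble(target_id = "T1",
                          site_id = paste0("s", seq_len(ns)),
                          total_M = stats::runif(ns, 1e-13, 2e-9))
  grid <- expand.grid(probe_id = probes, site_id = sites$site_id,
                      stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < 0.75
  keep[sample(nrow(grid), 1)] <- TRUE
  site <- tibble::as_tibble(grid[keep, ])
  site$target_id <- "T1"
  site$kd <- 10^stats::runif(nrow(site), -12, -8)
  site$dg_min <- NA_real_
  self <- tibble::tibble(probe_id = probes[stats::runif(np) < 0.5])
  self$kd <- 10^stats::runif(nrow(self), -1, 2)
  self$dg_min <- NA_real_
  if (np > 1) {
    pairs <- t(combn(seq_len(np), 2))
    cross <- tibble::tibble(
      probe_i = c(probes[pairs[, 1]], probes),
      probe_j = c(probes[pairs[, 2]], probes))
  } else {
    cross <- tibble::tibble(probe_i = probes, probe_j = probes)
  }
  cross <- cross[stats::runif(nrow(cross)) < 0.4, ]
  cross$kd <- 10^stats::runif(nrow(cross), -9, -6)
  cross$dg_min <- NA_real_
  list(kds = make_kds(site[, c("probe_id", "target_id", "site_id",
                               "kd", "dg_min")],
                      self, cross),
       probe_total = setNames(stats::runif(np, 1e-9, 2e-8), probes),
       sites = sites)
}

# ---- shared fixtures (computed once per session) ----------------------------
.cache <- new.env(parent = emptyenv())

toy_transcriptome <- function() {
  new_transcriptome(tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    gene_id = c("g1", "g1", "g2"),
    biotype = c("mRNA", "mRNA", "rRNA"),
    sequence = c("ATGGCGTACGTTAGCCGTATCGGCTAAGCTT",
                 "ATGGCGTACGTTAGCCGTAT",
                 "GGGCCCGGGCCCAAATTTGGGCCCGGGTTT")),
    isoform_counts = c(g1 = 2, g2 = 1))
}

arf4_fixture <- function() {
  if (is.null(.cache$fx)) {
    .cache$fx <- generate_fixture(arf4_like_scenario(),
                                  dir = file.path(tempdir(), "arf4_fx"))
  }
  .cache$fx
}

arf4_config <- function() {
  fx <- arf4_fixture()
  design_config(fasta = fx$paths$fasta, annotation = fx$paths$annotation,
                expression = fx$paths$expression, target_id = fx$target_id)
}

arf4_design <- function() {
  if (is.null(.cache$design)) {
    .cache$design <- run_design(arf4_config())
  }
  .cache$design
}

small_planted_fixture <- function(seed, identity_nt = c(15L, 14L)) {
  generate_fixture(fixture_spec(
    seed = seed, target_length = 120, n_decoys = 4,
    decoy_length = c(80, 160), include_rRNA_decoy = TRUE,
    plants = data.frame(window_start = c(10, 60), window_length = 20,
                        identity_nt = identity_nt,
                        decoy = c("1", "2"))),
    dir = tempfile())
}
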