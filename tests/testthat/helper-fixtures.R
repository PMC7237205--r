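# Shared fixtures and independent oracles, built in code at test time.

MOTIF_DOM2 <- "CCTCCCTAGCCACG"
MOTIF_CAST <- "AGGAATGCGTTGCA"

toy_genome <- function(seed = 1, lengths = c(chr1 = 2e5, chr2 = 1e5)) {
  generate_genome(seed, lengths)
}

toy_hotspot_genome <- function(seed = 1, n = 20, multi = 0,
                               lengths = c(chr1 = 4e5, chr2 = 2e5),
                               min_spacing = 15000) {
  g <- generate_genome(seed, lengths)
  plant_hotspots(g, n = n,
                 motifs = c(Dom2 = MOTIF_DOM2, Cast = MOTIF_CAST),
                 min_spacing = min_spacing, multi_motif_fraction = multi,
                 seed = seed + 1000)
}

# brute-force per-base center coverage oracle: accumulate the three center
# bases of each fragment into a per-base vector, then sum per bin
oracle_center_coverage <- function(fragments, chrom_len, bin) {
  base_mass <- numeric(chrom_len)
  for (i in seq_len(nrow(fragments))) {
    ctr <- floor((fragments$start[i] + fragments$end[i] - 1) / 2)
    for (b in (ctr - 1):(ctr + 1)) {
      if (b >= 0 && b < chrom_len) base_mass[b + 1] <- base_mass[b + 1] + 1
    }
  }
  n_bins <- ceiling(chrom_len / bin)
  vapply(seq_len(n_bins), function(k) {
    lo <- (k - 1) * bin + 1
    hi <- min(k * bin, chrom_len)
    sum(base_mass[lo:hi])
  }, numeric(1))
}

# brute-force single-linkage clustering oracle for anchor merging
oracle_merge <- function(pos, radius) {
  pos <- sort(pos)
  grp <- cumsum(c(1, diff(pos) > radius))
  vapply(split(pos, grp), function(p) floor((min(p) + max(p)) / 2),
         numeric(1))
}

# brute-force PWM scan: score every offset on both strands explicitly
oracle_scan <- function(seq, pwm_obj, threshold) {
  bases <- c("A", "C", "G", "T")
  L <- pwm_obj$length
  chars <- strsplit(seq, "")[[1]]
  rc <- function(x) rev(c(A = "T", C = "G", G = "C", T = "A")[x])
  out <- list()
  for (s0 in 0:(length(chars) - L)) {
    win <- chars[(s0 + 1):(s0 + L)]
    sc_f <- sum(pwm_obj$log_odds[cbind(1:L, match(win, bases))])
    sc_r <- sum(pwm_obj$log_odds[cbind(1:L, match(rc(win), bases))])
    if (sc_f >= threshold) {
      out[[length(out) + 1]] <- tibble::tibble(start = s0, strand = "+",
                                               score = sc_f)
    }
    if (sc_r >= threshold) {
      out[[length(out) + 1]] <- tibble::tibble(start = s0, strand = "-",
                                               score = sc_r)
    }
  }
  dplyr::bind_rows(out)
}

# exact permutation p-value for Spearman rho, independent enumeration
oracle_perm_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- combinat_perms(length(y))
  rhos <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
  mean(abs(rhos) >= obs - 1e-12)
}

combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

default_itc_schedule <- function() {
  itc_schedule(V0 = 200, M0 = 25, X0 = 343, injection_volumes = rep(2.5, 16))
}
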