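# Independent brute-force oracle for the TAATCY scanner: slide a window of
# width 6 over the sequence and test every hexamer against the consensus
# and its reverse complement with plain regular expressions. Deliberately
# shares no code with the scanner under test.
brute_force_taatcy <- function(seq) {
  L <- nchar(seq)
  if (L < 6L) return(data.frame(start = integer(), strand = character()))
  hex <- substring(seq, 1:(L - 5L), 6:L)
  fwd <- grepl("^TAATC[CT]$", hex)
  rev <- grepl("^[AG]GATTA$", hex)
  out <- rbind(
    data.frame(start = which(fwd) - 1L,
               strand = rep("+", sum(fwd)), stringsAsFactors = FALSE),
    data.frame(start = which(rev) - 1L,
               strand = rep("-", sum(rev)), stringsAsFactors = FALSE))
  out <- out[order(out$start, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# AT-rich random sequences so that motif hits are common
random_dna <- function(n, at_rich = TRUE) {
  p <- if (at_rich) c(0.35, 0.15, 0.15, 0.35) else rep(0.25, 4)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Gaussian multiplicative signals with a given CV, for direct signal-level
# simulations in the occupancy tests
noisy_signals <- function(n, mean, cv) {
  s <- sqrt(log(1 + cv^2))
  mean * stats::rlnorm(n, -s^2 / 2, s)
}
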