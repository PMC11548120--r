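# Independent reference implementations used to cross-check the package.
# These are written as literal step-by-step traces / alternative routes and
# deliberately share no code with the package internals.

# Literal per-sample trace of the drinking counter: compare each sample to
# the previous one, count drops of at least `th` while armed, reload the
# refractory window on a detection, always remember the last temperature.
drinking_trace <- function(temps, th = 2, w = 2) {
  r <- 0
  tlast <- temps[1]
  count <- 0
  fired <- integer()
  for (k in seq_along(temps)[-1]) {
    t <- temps[k]
    if (t < tlast - th && r == 0) {
      count <- count + 1
      r <- w
      fired <- c(fired, k)
    }
    if (r > 0) r <- r - 1
    tlast <- t
  }
  list(count = count, fired = fired)
}

# Alternative-route rumination credit computation: first segment the
# envelope into active onsets/ends by hysteresis, then walk the onset list
# crediting confirmed runs. Structured around segments rather than a
# per-sample state machine.
rumination_trace <- function(env, p) {
  s <- 0
  onsets <- integer()
  ends <- integer()
  for (n in seq_along(env)) {
    if (s == 0 && env[n] >= p$th_h) {
      s <- 1
      onsets <- c(onsets, n)
    }
    if (s == 1 && env[n] <= p$th_l) {
      s <- 0
      ends <- c(ends, n)
    }
  }
  L <- numeric()
  ongoing <- 0
  credit <- 0
  for (j in seq_along(onsets)) {
    if (j > 1) {
      len <- onsets[j] - onsets[j - 1]
      if (len < p$t_int_min || len > p$t_int_max) {
        ongoing <- 0
        L <- numeric()
      } else {
        L <- c(L, len)
        if (length(L) > p$k) L <- L[-1]
        if (length(L) == p$k && min(L) / max(L) > 1 - p$delta_t_im) {
          if (ongoing == 0) {
            credit <- credit + sum(L)
            ongoing <- 1
          } else {
            credit <- credit + len
          }
        }
      }
    }
    e <- ends[ends >= onsets[j]]
    if (length(e)) {
      act <- e[1] - onsets[j]
      if (act < p$t_act_min || act > p$t_act_max) {
        ongoing <- 0
        L <- numeric()
      }
    }
  }
  credit
}

# Bit-level packet oracle: renders every field as a binary string by
# repeated division, concatenates, zero-pads to 51 bytes and converts
# nibble-wise to hex. Independent of the codec's raw-vector packing.
oracle_bin <- function(v, width) {
  out <- character(width)
  for (i in width:1) {
    out[i] <- as.character(v %% 2)
    v <- v %/% 2
  }
  paste(out, collapse = "")
}

oracle_packet_hex <- function(packet_id, temp_code, drink, act3, peak12,
                              rum_code, hr12, fw, status, batt_code) {
  bits <- paste0(
    oracle_bin(packet_id, 16),
    oracle_bin(temp_code, 12),
    oracle_bin(drink, 8),
    paste(vapply(act3, oracle_bin, "", width = 8), collapse = ""),
    paste(vapply(peak12, oracle_bin, "", width = 4), collapse = ""),
    oracle_bin(rum_code, 12),
    paste(vapply(hr12, oracle_bin, "", width = 4), collapse = ""),
    oracle_bin(fw, 8),
    oracle_bin(status, 8),
    oracle_bin(batt_code, 8))
  bits <- paste0(bits, strrep("0", 51 * 8 - nchar(bits)))
  nibbles <- substring(bits, seq(1, nchar(bits), 4), seq(4, nchar(bits), 4))
  paste(vapply(nibbles, function(nb)
    format(as.hexmode(strtoi(nb, base = 2)), width = 1), ""),
    collapse = "")
}
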