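# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_snpher <- function(class, msg, ...) {
  stop(structure(class = c(class, "snpher_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# derive a sub-stream seed; keeps results reproducible while letting
# genotypes / effects / residuals be re-drawn independently
stream_seed <- function(seed, stream) {
  offsets <- c(genotypes = 11L, effects = 29L, residuals = 47L,
               ascertain = 83L, artifact = 131L, perm = 173L)
  s <- (as.integer(seed) %% 1000000000L) * 2L + offsets[[stream]]
  as.integer(s %% .Machine$integer.max)
}

sample_ids <- function(n, prefix = "S") {
  idx <- formatC(seq_len(n), width = nchar(n), flag = "0")
  data.frame(fid = paste0("F", prefix, idx), iid = paste0(prefix, idx),
             stringsAsFactors = FALSE)
}

# approximate relative physical lengths of human autosomes 1..22,
# used as default weights when scattering simulated SNPs over chromosomes
autosome_lengths <- function() {
  c(247.2, 242.8, 199.4, 191.3, 180.8, 170.9, 158.8, 146.3, 140.4, 135.4,
    134.5, 132.3, 114.1, 106.4, 100.3, 88.8, 78.7, 76.1, 63.8, 62.4,
    46.9, 49.7)
}
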