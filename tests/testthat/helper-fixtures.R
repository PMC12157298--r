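# hand-built sensor frames for preprocessing tests
make_frames <- function(c1, posture = "upright", sub_variant = "none",
                        participant = "P01") {
  n <- length(c1)
  data.frame(t = seq(0, by = 0.5, length.out = n), participant = participant,
             posture = rep_len(posture, n),
             sub_variant = rep_len(sub_variant, n),
             c1 = c1, c2 = rep(50, n), c3 = rep(45, n), c4 = rep(42, n),
             stringsAsFactors = FALSE)
}

# two well-separated clusters in 4-D: a linearly separable 2-class toy set
toy_separable <- function(n_per = 20, seed = 1) {
  set.seed(seed)
  f <- rbind(matrix(rnorm(n_per * 4, mean = 0, sd = 0.05), ncol = 4),
             matrix(rnorm(n_per * 4, mean = 1, sd = 0.05), ncol = 4))
  colnames(f) <- c("c1", "c2", "c3", "c4")
  dynsit:::new_dataset(f, rep(c(0L, 1L), each = n_per))
}
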