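#' Stratified permuted-block randomisation list
#'
#' Generates a 1:1:1 allocation sequence for the three arms within each
#' stratum using randomly permuted blocks of fixed size, the scheme used to
#' balance arms within union x sex cells. Within every complete block each
#' arm appears exactly `block_size/3` times, so the running per-arm imbalance
#' inside a stratum never exceeds `2 * block_size / 3`.
#'
#' @param strata character vector of stratum labels.
#' @param block_size block length, a multiple of 3.
#' @param n_per_stratum non-negative integer allocation-list length for each
#'   stratum (recycled if length 1).
#' @param seed integer; the sequence is deterministic given the seed.
#'
#' @return data.frame of class `allocation_list` with columns `stratum`,
#'   `position` (1-based within stratum), `block` and `arm`.
#' @export
generate_randomisation_list <- function(strata, block_size = 6,
                                        n_per_stratum, seed = 1L) {
  assert_count(block_size, "block_size")
  if (block_size %% 3L != 0L)
    stop_cldagate("`block_size` must be divisible by 3: each complete block ",
                  "holds block_size/3 allocations per arm")
  n_per_stratum <- rep_len(as.integer(n_per_stratum), length(strata))
  if (any(n_per_stratum < 0)) stop_cldagate("`n_per_stratum` must be >= 0")

  with_seed(seed, {
    out <- lapply(seq_along(strata), function(i) {
      n <- n_per_stratum[i]
      if (n == 0L) return(NULL)
      n_blocks <- ceiling(n / block_size)
      arms <- unlist(lapply(seq_len(n_blocks), function(b)
        sample(rep(ARMS, block_size %/% 3L))), use.names = FALSE)[seq_len(n)]
      data.frame(stratum = strata[i], position = seq_len(n),
                 block = (seq_len(n) - 1L) %/% block_size + 1L,
                 arm = arms, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    class(res) <- c("allocation_list", "data.frame")
    attr(res, "block_size") <- block_size
    attr(res, "seed") <- as.integer(seed)
    res
  })
}
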