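# Shared fixtures, built in code.  small_sim() is memoized because several
# test files exercise different stages of the same synthetic data set.

small_truth <- function(...) {
  args <- utils::modifyList(
    list(n_sires = 50L, n_genotyped = 40L, n_offspring = 1200L,
         n_snps = 150L, seed = 11L),
    list(...)
  )
  do.call(sim_truth, args)
}

.small_sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.small_sim_cache$sim)) {
    .small_sim_cache$sim <- simulate_dataset(small_truth())
  }
  .small_sim_cache$sim
}

# 20 complete days x 24 h of hourly weather for one station, deterministic
flat_weather <- function(n_days = 20L, station = "ST1", start = "2016-03-01",
                         temp = NULL, rh = NULL) {
  ts <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
            by = "1 hour", length.out = n_days * 24L)
  n <- length(ts)
  data.frame(
    station = station, timestamp = ts,
    temp_c = if (is.null(temp)) 10 + sin(seq_len(n) / 5) else
      rep_len(temp, n),
    rh = if (is.null(rh)) 60 + 10 * cos(seq_len(n) / 7) else rep_len(rh, n),
    stringsAsFactors = FALSE
  )
}

# independent kinship oracle: memoized coancestry recursion, A = 2 * phi
phi_oracle <- function(ped) {
  ped$animal <- as.character(ped$animal)
  memo <- new.env(parent = emptyenv())
  sire <- stats::setNames(as.character(ped$sire), ped$animal)
  dam <- stats::setNames(as.character(ped$dam), ped$animal)
  born <- stats::setNames(seq_len(nrow(ped)), ped$animal)  # input order
  phi <- function(a, b) {
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) return(0)
    key <- paste(sort(c(a, b)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (a == b) {
      0.5 * (1 + phi(sire[[a]], dam[[a]]))
    } else {
      yng <- if (born[[a]] >= born[[b]]) a else b
      old <- if (identical(yng, a)) b else a
      0.5 * (phi(sire[[yng]], old) + phi(dam[[yng]], old))
    }
    memo[[key]] <- val
    val
  }
  ids <- ped$animal
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in ids) for (j in ids) A[i, j] <- 2 * phi(i, j)
  A
}

# random pedigree with parents preceding offspring (founder fraction fixed)
random_pedigree <- function(n, seed) {
  set.seed(seed)
  id <- sprintf("A%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  n_founder <- max(4L, round(n / 3))
  for (i in seq.int(n_founder + 1L, n)) {
    sire[i] <- sample(id[seq_len(i - 1L)], 1L)
    dam[i] <- sample(setdiff(id[seq_len(i - 1L)], sire[i]), 1L)
  }
  data.frame(animal = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
}
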