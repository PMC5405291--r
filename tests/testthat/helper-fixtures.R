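# Shared fixtures, built in code.

# a week of identical, perfectly regular nights: TIB 480, TST 408 (SE 85)
regular_week <- function(start = "2024-03-01", n = 7, sol = 30, waso = 30,
                         twak = 12, bed = "23:00", arise = "07:00") {
  diary_entry(
    date = as.Date(start) + seq_len(n) - 1,
    bed_time = rep(bed, n), try_sleep_time = rep(bed, n),
    sol = rep(sol, n), n_awakenings = rep(1L, n), waso = rep(waso, n),
    final_wake_time = rep(format_clock(parse_clock(arise) - twak), n),
    arising_time = rep(arise, n), quality = rep(5L, n),
    used_medication = rep(FALSE, n))
}

# a one-row weekly summary with given TIB/TST means
summary_of <- function(mean_tib, mean_tst, n_entries = 7L, mean_se = 80) {
  tibble::tibble(n_entries = n_entries, mean_tib = mean_tib,
                 mean_tst = mean_tst, mean_sol = 30, mean_waso = 30,
                 mean_twak = 10, mean_se = mean_se, mean_quality = 5,
                 mean_awakenings = 1.5)
}

# brute-force Pearson chi-square from expected counts
chi2_brute <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}
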