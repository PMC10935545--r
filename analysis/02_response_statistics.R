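#!/usr/bin/env Rscript
# Stage 2: single-cell response statistics on the fully loaded 100 uM
# run -- induction times, peak times and amplitudes, their CVs, and
# the dependence of the mother-cell peak amplitude on the number of
# barrier cells (using the partially loaded device, where that number
# actually varies at treatment time).

suppressMessages({library(trenchshield); library(data.table)})
dir.create("results", showWarnings = FALSE)
say <- function(...) message(sprintf(...))

tt <- read_tracks("results/tracks/full_100.csv")
m <- tt[cell_index == 0]
base <- m[time < 0, mean(reporter)]

per_mother <- m[, {
  pk <- detect_peak(time, reporter, window = 135)
  list(induction = induction_time(time, reporter, 1480),
       peak_time = pk$peak_time, amplitude = pk$peak_amplitude)
}, by = trench_id]

say("mothers: %d; induction time %.1f +/- %.1f min (%.0f%% cross 1480 a.u.)",
    nrow(per_mother),
    mean(per_mother$induction, na.rm = TRUE),
    sd(per_mother$induction, na.rm = TRUE),
    100 * mean(!is.na(per_mother$induction)))
say("peak time %.1f +/- %.1f min, amplitude %.0f +/- %.0f a.u.",
    mean(per_mother$peak_time, na.rm = TRUE),
    sd(per_mother$peak_time, na.rm = TRUE),
    mean(per_mother$amplitude, na.rm = TRUE),
    sd(per_mother$amplitude, na.rm = TRUE))

cvs <- data.frame(
  quantity = c("induction_time", "peak_time", "peak_amplitude"),
  cv = c(cv(per_mother$induction, na.rm = TRUE),
         cv(per_mother$peak_time, na.rm = TRUE),
         cv(per_mother$amplitude, na.rm = TRUE)))
say("CVs: %s", paste(sprintf("%s %.2f", cvs$quantity, cvs$cv),
                     collapse = ", "))

# amplitude against peak time (the spread is correlated, not random)
ok <- complete.cases(per_mother[, .(peak_time, amplitude)])
say("cor(amplitude, peak time) = %.2f",
    cor(per_mother$peak_time[ok], per_mother$amplitude[ok]))

# partial loading: amplitude vs barrier count at treatment
tp <- read_tracks("results/tracks/partial_100.csv")
mp <- tp[cell_index == 0]
basep <- mp[time < 0, mean(reporter)]
amp <- mp[time > 0 & time <= 60, .(amp = max(reporter) - basep),
          by = trench_id]
B0 <- tp[time >= -9 & time <= 9,
         .N, by = .(trench_id, frame)][, .(B = round(mean(N)) - 1),
                                       by = trench_id]
byB <- merge(amp, B0, by = "trench_id")[
  , .(amplitude = mean(amp), n = .N), keyby = B]
print(byB)
fwrite(per_mother, "results/response_summary.csv")
fwrite(byB, "results/amplitude_by_barrier.csv")
say("kendall(amplitude, barriers) = %.2f  [written to results/]",
    merge(amp, B0, by = "trench_id")[, cor(B, amp, method = "kendall")])
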