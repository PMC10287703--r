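# fixtures built in code: tiny minute/daily frames and CSV writers

minute_row <- function(date = "2023-01-01", time = "08:00:00",
                       upload_status = "H", ima = 100,
                       weight_bearing_s = 0, sedentary_s = 0, standing_s = 0,
                       lpa_s = 0, mpa_s = 0, vpa_s = 0, steps = 0) {
  data.frame(date = as.Date(date), time = time,
             upload_status = upload_status, ima = ima,
             weight_bearing_s = weight_bearing_s, sedentary_s = sedentary_s,
             standing_s = standing_s, lpa_s = lpa_s, mpa_s = mpa_s,
             vpa_s = vpa_s, steps = steps, stringsAsFactors = FALSE)
}

# a daily frame of n consecutive days with given steps and activity seconds
make_days <- function(steps, mpa_s = 0, vpa_s = 0, sedentary_s = 20000,
                      lpa_s = 3600, start = "2023-01-01") {
  n <- length(steps)
  data.frame(date = as.Date(start) + seq_len(n) - 1,
             steps = steps,
             sedentary_s = rep_len(sedentary_s, n),
             lpa_s = rep_len(lpa_s, n),
             mpa_s = rep_len(mpa_s, n),
             vpa_s = rep_len(vpa_s, n),
             stringsAsFactors = FALSE)
}

# a week of days whose APV equals `apv` (via step bands, negligible ME)
week_for_apv <- function(apv, start = "2023-01-01") {
  steps <- c(3000, 6000, 8000, 11000, 13000)[apv + 1]
  make_days(steps, start = start)
}

write_mox_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  out <- df
  names(out) <- c("Date", "Time", "UploadStatus", "IMA", "WeightBearing",
                  "Sedentary", "Standing", "LPA", "MPA", "VPA", "Steps")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  path
}
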