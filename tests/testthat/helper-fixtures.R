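# Shared fixtures, all generated in code.

# small noiseless phantom for fast unit tests
tiny_phantom <- function(lesion_type = "none", seed = 1, ...) {
  make_phantom(shape = c(48, 48), n_frames = 120, frame_interval = 0.5,
               lesion_type = lesion_type, seed = seed, ...)
}

# closed-form mean-gradient-to-peak oracle: root-bracket the gamma-variate at
# baseline + frac * ymax, then endpoint quotient on the continuous curve
mgp_oracle <- function(model, frac = 0.05) {
  f <- function(tt) {
    gamma_variate(tt, model) - (model$baseline + frac * model$ymax)
  }
  ts <- stats::uniroot(f, c(model$t0, model$tpk), tol = 1e-12)$root
  list(t_start = ts,
       mgp = ((1 - frac) * model$ymax) / (model$tpk - ts))
}

# minimal explicit-VR little-endian multi-frame DICOM file, written raw
write_test_dicom <- function(path, frames, frame_time_ms = NULL,
                             cine_rate = NULL, bits = 8) {
  nf <- dim(frames)[1]; rows <- dim(frames)[2]; cols <- dim(frames)[3]
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                              endian = "little")
  el_short <- function(g, e, vr, body) {
    if (length(body) %% 2 == 1) {
      body <- c(body, if (vr %in% c("IS", "DS", "UI", "CS")) charToRaw(" ")
                else as.raw(0))
    }
    c(u16(g), u16(e), charToRaw(vr), u16(length(body)), body)
  }
  el_long <- function(g, e, vr, body) {
    c(u16(g), u16(e), charToRaw(vr), as.raw(c(0, 0)), u32(length(body)), body)
  }
  txt <- function(s) charToRaw(s)

  meta <- c(
    el_short(0x0002, 0x0010, "UI", txt("1.2.840.10008.1.2.1"))
  )
  ds <- c(
    el_short(0x0028, 0x0008, "IS", txt(as.character(nf))),
    el_short(0x0028, 0x0010, "US", u16(rows)),
    el_short(0x0028, 0x0011, "US", u16(cols)),
    el_short(0x0028, 0x0100, "US", u16(bits))
  )
  if (!is.null(frame_time_ms)) {
    ds <- c(ds, el_short(0x0018, 0x1063, "DS", txt(as.character(frame_time_ms))))
  }
  if (!is.null(cine_rate)) {
    ds <- c(ds, el_short(0x0018, 0x0040, "IS", txt(as.character(cine_rate))))
  }
  # pixel data row-major per frame
  px <- integer(0)
  for (f in seq_len(nf)) px <- c(px, as.integer(t(frames[f, , ])))
  body <- writeBin(px, raw(), size = bits / 8, endian = "little")
  ds <- c(ds, el_long(0x7fe0, 0x0010, "OB", body))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

# brute-force two-way ANOVA ICC oracle: sums of squares by definition
icc_bruteforce <- function(x, form = "single") {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ssr <- ssc <- sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sse <- sse + (x[i, j] - mean(x[i, ]) - mean(x[, j]) + grand)^2
  }
  for (i in seq_len(n)) ssr <- ssr + k * (mean(x[i, ]) - grand)^2
  for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - grand)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  if (form == "single") icc1 else icc1 * k / (1 + (k - 1) * icc1)
}

# ratings table built from explicit matrices (bypasses the generator)
ratings_from_matrix <- function(m, truth) {
  df <- tibble::as_tibble(as.data.frame(m))
  names(df) <- paste0("rater_", seq_len(ncol(m)))
  out <- dplyr::bind_cols(tibble::tibble(case_id = seq_len(nrow(m)),
                                         truth = truth), df)
  structure(out, class = c("ratings_table", class(out)))
}
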