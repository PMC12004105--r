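# Independent scalar transcription of the 1987 Canadian FWI System daily
# update equations (Van Wagner's structure, standard constant set).  Written
# directly from the equation set, one scalar function per index, before the
# package engine; kept deliberately naive as the oracle for the engine tests.

ref_ffmc <- function(ffmc0, temp, rh, ws, prec) {
  wmo <- 147.2 * (101 - ffmc0) / (59.5 + ffmc0)
  if (prec > 0.5) {
    ra <- prec - 0.5
    if (wmo > 150) {
      wmo <- wmo +
        42.5 * ra * exp(-100 / (251 - wmo)) * (1 - exp(-6.93 / ra)) +
        0.0015 * (wmo - 150)^2 * sqrt(ra)
    } else {
      wmo <- wmo + 42.5 * ra * exp(-100 / (251 - wmo)) * (1 - exp(-6.93 / ra))
    }
    if (wmo > 250) wmo <- 250
  }
  ed <- 0.942 * rh^0.679 + 11 * exp((rh - 100) / 10) +
    0.18 * (21.1 - temp) * (1 - exp(-0.115 * rh))
  if (wmo > ed) {
    z <- 0.424 * (1 - (rh / 100)^1.7) +
      0.0694 * sqrt(ws) * (1 - (rh / 100)^8)
    x <- z * 0.581 * exp(0.0365 * temp)
    wm <- ed + (wmo - ed) / 10^x
  } else {
    ew <- 0.618 * rh^0.753 + 10 * exp((rh - 100) / 10) +
      0.18 * (21.1 - temp) * (1 - exp(-0.115 * rh))
    if (wmo < ew) {
      z <- 0.424 * (1 - ((100 - rh) / 100)^1.7) +
        0.0694 * sqrt(ws) * (1 - ((100 - rh) / 100)^8)
      x <- z * 0.581 * exp(0.0365 * temp)
      wm <- ew - (ew - wmo) / 10^x
    } else {
      wm <- wmo
    }
  }
  out <- 59.5 * (250 - wm) / (147.2 + wm)
  min(max(out, 0), 101)
}

ref_dmc <- function(dmc0, temp, rh, prec, mon) {
  el <- c(6.5, 7.5, 9.0, 12.8, 13.9, 13.9, 12.4, 10.9, 9.4, 8.0, 7.0, 6.0)
  t <- max(temp, -1.1)
  rk <- 1.894 * (t + 1.1) * (100 - rh) * el[mon] * 1e-4
  if (prec > 1.5) {
    rw <- 0.92 * prec - 1.27
    wmi <- 20 + 280 / exp(0.023 * dmc0)
    if (dmc0 <= 33) {
      b <- 100 / (0.5 + 0.3 * dmc0)
    } else if (dmc0 <= 65) {
      b <- 14 - 1.3 * log(dmc0)
    } else {
      b <- 6.2 * log(dmc0) - 17.2
    }
    wmr <- wmi + 1000 * rw / (48.77 + b * rw)
    pr <- 43.43 * (5.6348 - log(wmr - 20))
  } else {
    pr <- dmc0
  }
  if (pr < 0) pr <- 0
  pr + rk
}

ref_dc <- function(dc0, temp, prec, mon) {
  fl <- c(-1.6, -1.6, -1.6, 0.9, 3.8, 5.8, 6.4, 5.0, 2.4, 0.4, -1.6, -1.6)
  t <- max(temp, -2.8)
  pe <- (0.36 * (t + 2.8) + fl[mon]) / 2
  if (pe < 0) pe <- 0
  if (prec > 2.8) {
    rw <- 0.83 * prec - 1.27
    smi <- 800 * exp(-dc0 / 400)
    dr <- dc0 - 400 * log(1 + 3.937 * rw / smi)
    if (dr < 0) dr <- 0
    out <- dr + pe
  } else {
    out <- dc0 + pe
  }
  max(out, 0)
}

ref_isi <- function(ffmc, ws) {
  fm <- 147.2 * (101 - ffmc) / (59.5 + ffmc)
  fw <- exp(0.05039 * ws)
  ff <- 91.9 * exp(-0.1386 * fm) * (1 + fm^5.31 / 4.93e7)
  0.208 * fw * ff
}

ref_bui <- function(dmc, dc) {
  if (dmc == 0 && dc == 0) return(0)
  if (dmc <= 0.4 * dc) {
    out <- 0.8 * dmc * dc / (dmc + 0.4 * dc)
  } else {
    out <- dmc - (1 - 0.8 * dc / (dmc + 0.4 * dc)) *
      (0.92 + (0.0114 * dmc)^1.7)
  }
  max(out, 0)
}

ref_fwi <- function(isi, bui) {
  fd <- if (bui > 80) 1000 / (25 + 108.64 * exp(-0.023 * bui)) else
    0.626 * bui^0.809 + 2
  b <- 0.1 * isi * fd
  if (b > 1) exp(2.72 * (0.434 * log(b))^0.647) else b
}

# One daily update from yesterday's three codes; returns the six indices.
ref_fwi_step <- function(ffmc0, dmc0, dc0, temp, rh, ws, prec, mon) {
  ffmc <- ref_ffmc(ffmc0, temp, rh, ws, prec)
  dmc <- ref_dmc(dmc0, temp, rh, prec, mon)
  dc <- ref_dc(dc0, temp, prec, mon)
  isi <- ref_isi(ffmc, ws)
  bui <- ref_bui(dmc, dc)
  c(ffmc = ffmc, dmc = dmc, dc = dc, isi = isi, bui = bui,
    fwi = ref_fwi(isi, bui))
}

# Run a whole weather sequence (data.frame: temp, rh, ws, prec, mon).
ref_fwi_run <- function(wx, ffmc0 = 85, dmc0 = 6, dc0 = 15) {
  out <- matrix(NA_real_, nrow(wx), 6,
                dimnames = list(NULL, c("ffmc", "dmc", "dc", "isi", "bui", "fwi")))
  for (i in seq_len(nrow(wx))) {
    v <- ref_fwi_step(ffmc0, dmc0, dc0, wx$temp[i], wx$rh[i], wx$ws[i],
                      wx$prec[i], wx$mon[i])
    out[i, ] <- v
    ffmc0 <- v[["ffmc"]]; dmc0 <- v[["dmc"]]; dc0 <- v[["dc"]]
  }
  as.data.frame(out)
}
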