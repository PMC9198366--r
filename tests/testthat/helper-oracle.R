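# Cross-check harness against an established wavelet library (PyWavelets,
# invoked through the `python` on PATH). One python process computes every
# reference quantity and returns them as JSON.
#
# Convention bridges (PyWavelets applies the time-reversed filters, so its
# outputs map onto ours on the time-reversed input):
#  * filters: our analysis_lowpass equals pywt's rec_lo tap-for-tap.
#  * one-level decimated transform, order p: pywt's periodization cA/cD on x
#    equal circ_shift(rev(ours on shiftr(rev(x), p %% 2)), floor(p/2) + p %% 2).
#  * undecimated bands, level j: pywt's swt(norm=False) on rev(x), reversed,
#    equals our band circularly shifted by -(Ltap/2 - 1) * (2^j - 1).
run_pywt_oracle <- function(signals, orders_level1 = c(3, 8), swt_levels = 3) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  sig_path <- file.path(dir, "signals.txt")
  writeLines(vapply(signals, function(s) paste(sprintf("%.17g", s), collapse = " "),
                    character(1)), sig_path)
  out_path <- file.path(dir, "oracle.json")
  script <- file.path(dir, "oracle.py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "import pywt",
    sprintf("sig_path, out_path = %s, %s", deparse(sig_path), deparse(out_path)),
    "signals = [np.array([float(v) for v in l.split()]) for l in open(sig_path)]",
    "out = {'rec_lo': {}, 'dwt': [], 'swt': [], 'roundtrip': []}",
    "for p in range(1, 11):",
    "    out['rec_lo'][str(p)] = list(pywt.Wavelet(f'db{p}').rec_lo)",
    sprintf("orders = %s", paste0("[", paste(orders_level1, collapse = ","), "]")),
    "for x in signals:",
    "    entry = {}",
    "    for p in orders:",
    "        cA, cD = pywt.dwt(x, f'db{p}', mode='periodization')",
    "        entry[str(p)] = {'cA': list(cA), 'cD': list(cD)}",
    "    out['dwt'].append(entry)",
    sprintf("    sw = pywt.swt(x[::-1], 'db8', level=%d, norm=False, trim_approx=True)", swt_levels),
    "    out['swt'].append({'a': list(sw[0][::-1]),",
    sprintf("                       'd': [list(sw[-j][::-1]) for j in range(1, %d + 1)]})", swt_levels),
    "    rec = pywt.waverec(pywt.wavedec(x, 'db8', mode='periodization', level=2), 'db8', mode='periodization')",
    "    out['roundtrip'].append(list(rec))",
    "json.dump(out, open(out_path, 'w'))"
  ), script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("python oracle run failed (PyWavelets required)")
  jsonlite::read_json(out_path, simplifyVector = TRUE)
}
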