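# Independent reference implementation of the affine-invariant distance and
# the Karcher mean, in Python/scipy (Schur-based matrix functions, a fully
# separate code path from the package's eigen-based R implementation).

spd_oracle_script <- function() {
  path <- file.path(tempdir(), "spd_oracle.py")
  if (!file.exists(path)) {
    writeLines(c(
      "import json, sys",
      "import numpy as np",
      "from scipy.linalg import sqrtm, logm, expm, eigvalsh",
      "sets = json.load(open(sys.argv[1]))",
      "out = []",
      "for s in sets:",
      "    ms = [np.array(m) for m in s]",
      "    w = eigvalsh(ms[1], ms[0])",
      "    d = float(np.sqrt(np.sum(np.log(w) ** 2)))",
      "    M = sum(ms) / len(ms)",
      "    for _ in range(300):",
      "        Ms = np.real(sqrtm(M))",
      "        Mis = np.linalg.inv(Ms)",
      "        T = sum(np.real(logm(Mis @ P @ Mis)) for P in ms) / len(ms)",
      "        if np.linalg.norm(T) < 1e-12:",
      "            break",
      "        M = Ms @ np.real(expm(T)) @ Ms",
      "    out.append({'dist01': d, 'mean': np.real(M).tolist()})",
      "json.dump(out, open(sys.argv[2], 'w'))"
    ), path)
  }
  path
}

# sets: list of lists of SPD matrices. Returns per set the oracle's
# distance between the first two matrices and the oracle's Karcher mean.
spd_oracle <- function(sets) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(sets, fin, digits = NA)
  status <- system2("python", c(spd_oracle_script(), fin, fout),
                    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  jsonlite::fromJSON(fout, simplifyVector = FALSE)
}
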