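# bacslbp

Finger-vein verification by block-averaged centre-symmetric binary coding.

Near-infrared finger images show the vein network as dark curvilinear
ridges on a brighter, low-contrast background. This package turns such a
pre-cropped grayscale image into a short binary codeword and verifies
identities by comparing codewords — no vein segmentation, no training. It
is aimed at people building or studying lightweight biometric matchers:
the whole pipeline (encode, enroll, match, evaluate) is plain R, fully
seeded, and testable end-to-end on a bundled synthetic vein-image
generator.

## Method

For an `A x B` image and block spec `a x b`:

1. zero-pad to block multiples and pool to the `p x q` block-mean matrix
   `I'`, `p = ceiling(A/a)`, `q = ceiling(B/b)`;
2. partition `I'` (zero-padded) into non-overlapping 3x3 tiles; in each
   tile read the border clockwise from the top-left as `n1..n8` and emit
   4 bits, bit `j = 1` iff `n_j >= n_{j+4}` (each centrosymmetric pair is
   one order comparison);
3. concatenate tiles row-major into the codeword `x = x_1 || ... || x_m`
   of length `L = 4 * ceiling(p/3) * ceiling(q/3)`.

Enrollment keeps the codes of a subject's first `N` images (default 6).
The matching score of a probe `x` against templates `{x_n}` is

    score = min_n hamming(x, x_n) / L

and the probe is accepted iff `score <= DT` (default 0.19). Verification
performance is reported as FAR/FRR over a threshold grid, the interpolated
equal error rate (EER), and recognition rates at chosen thresholds.

## Worked example

```r
library(bacslbp)
ds  <- generate_dataset(synth_config(n_subjects = 10, seed = 42))
rep <- run_protocol(ds, N = 6, spec = block_spec(3, 8))
summary(rep)
```

```
vein verification report: 10 subjects, N = 6 templates, block spec 3x8, L = 480 bits
  genuine trials:  60
  impostor trials: 540
  EER: 1.67%

recognition rates by decision threshold:
   dt n_genuine false_rejects intra_rate n_impostor false_accepts inter_rate
 0.18        60            14      76.67        540             0        100
 0.19        60            13      78.33        540             0        100
 0.20        60             9      85.00        540             0        100
 0.21        60             8      86.67        540             0        100
```

Each of the 10 synthetic fingers contributes 12 samples: 6 enrolled as
templates, 6 as probes. Every probe is scored against its own finger (60
genuine, 1:1 trials) and against each of the other 9 fingers (540
impostor, 1:N trials). The EER of 1.67% is the interpolated threshold
point where false acceptances and false rejections balance; the table
shows the trade-off the decision threshold sweeps out — raising `DT`
accepts more genuine probes (intra rate rises) at the cost of eventually
accepting impostors (inter rate falls). `plot(rep)` draws the FAR/FRR
curves.

Single images work the same way via `encode_image()`, `template_set()`,
`match_score()` and `verify_probe()`; codes serialise to a plain-text
format with `write_veincodes()`.

There is also a command-line front end (installed at
`inst/scripts/bacslbp`), with subcommands `encode`, `enroll`, `match`,
`evaluate` and `synth`:

```sh
Rscript inst/scripts/bacslbp synth --subjects 10 --samples 12 --seed 42 --out ds/
Rscript inst/scripts/bacslbp evaluate --dir ds/ --templates 6 --block-spec 3x8 --out report.json
```

Note on formats: image input is PNG (or TIFF with the tiff package);
BMP — common in the original acquisition databases — is not readable by
any of the package's dependencies, so convert BMP sources to PNG first.

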