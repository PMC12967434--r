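# ulnakin

Automated 3-D analysis of ulnar-sided wrist kinematics from dynamic
(4-D) CT bone surfaces.

Dynamic wrist disorders — ulnocarpal impaction and distal radioulnar joint
(DRUJ) instability — are positional: they can be invisible in a static
neutral scan and obvious only at the extremes of motion. Given segmented
bone surface meshes (radius, ulna, lunate, triquetrum, capitate) tracked
across dynamic CT frames, `ulnakin` computes, per frame:

| parameter | meaning | units |
|---|---|---|
| `uv3d` | 3-D ulnar variance: height difference between the most distal ulnar head point (styloid removed) and the most distal sigmoid-notch point, along the radius' long axis | mm |
| `ucp_l`, `ucp_t` | ulnocarpal proximity: shortest surface distance ulna→lunate / ulna→triquetrum | mm |
| `mru3d` | modified radioulnar line: ulnar-head protrusion past the palmar-radial line, over notch width | % |
| `epi3d` | epicentre method: offset of the ulnar long-axis/distal-cortex intersection along the notch chord, over notch width | % |

together with a signed wrist angle per movement (sagittal capitoradial for
flexion–extension, coronal capitoradial for radioulnar deviation, axial
ulnoradial for pronation–supination) and delta values relative to the
neutral frame. Dorsal dislocation of the radius is positive; a positive
`uv3d` is an ulna-plus wrist.

The package contains the full measurement chain: anatomical frames with
left-to-right side normalization, automatic landmark detection (ulnar
styloid removal, sigmoid-notch classification by surface curvature above
0.1/mm, notch margins, ulnar epicentre by axis/cortex intersection),
exact mesh-to-mesh minimum distance, point-to-plane ICP registration of
static bones to dynamic frames, angle-binned cohort summaries
(median/IQR, Shapiro–Wilk reporting gate, minimum-wrist-count masking),
mesh I/O (STL, PLY, labeled NIfTI volumes via marching tetrahedra), and a
parametric synthetic-wrist generator with exact analytic ground truth for
every landmark and parameter.

## Worked example

Generate a synthetic wrist with known ground truth, simulate a
pronation–supination sequence, and measure it:

```r
library(ulnakin)

w <- generate_wrist(wrist_params(uv3d = -0.4, g_lunate = 3.2,
                                 g_triquetrum = 6.9))
s <- simulate_motion(w, motion_params("PS", n_frames = 11))
series <- evaluate_sequence(s)
round(series[c(1, 6, 11),
             c("wrist_angle_deg", "uv3d_mm", "ucp_l_mm", "ucp_t_mm",
               "mru3d_pct", "epi3d_pct")], 2)
#>    wrist_angle_deg uv3d_mm ucp_l_mm ucp_t_mm mru3d_pct epi3d_pct
#> 1              -50   -1.42     3.15     5.95     12.73     -7.68
#> 6                0   -0.32     3.20     6.90     20.16      0.00
#> 11              50   -1.42     3.25     7.85     27.60      7.68
```

At 50° pronation (frame 1) the radius sits palmar relative to the ulnar
head (`epi3d` −7.7% of notch width; the pronation-to-supination excursion
spans 15.4%), the triquetrum has approached the ulna (6.9 → 5.95 mm) and
the ulnar variance has dropped by 1.1 mm; at 50° supination the
palmar-dorsal translation reverses while the triquetrum recedes. The
phantom's neutral pose puts the epicentre exactly over the notch midpoint
(`epi3d` 0 at 0°). Each value agrees with the phantom's analytic ground
truth (`s$truth`) to within mesh tolerance — for this sequence the DRUJ
percentages are recovered to better than 0.1 percentage points and
`uv3d` to 0.08 mm. `write_parameter_series(series, "ps.csv")` writes the per-frame
CSV; `bin_by_angle()` + `write_summary_table()` +
`plot_parameter_curves()` produce cohort tables and parameter-versus-angle
figures with 22-wrist masking.

A thin command-line interface wraps the same functions
(`inst/scripts/ulnakin`): `ulnakin run` measures a wrist from STL/PLY
meshes, `ulnakin summarize` pools per-wrist CSVs, `ulnakin synth` writes
synthetic fixtures.

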