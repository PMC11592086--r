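# semgrasp

Compliant grasp simulation from surface EMG for an underactuated
prosthetic finger.

Most compliant prosthetic-hand controllers pick their stiffness from
the *object* (via contact sensing), which can contradict the wearer's
intent. This package simulates the alternative: decode both the grasp
force **and** the muscle stiffness from the wearer's surface EMG, and
schedule the impedance controller from them — so a fragile paper cup
is taken slowly and gently, a rigid plastic cup quickly and firmly,
because that is how the wearer's muscles gripped it.

The simulated chain, every stage of which is exposed as package
functions:

1. **sEMG → activation.** Synthetic 8-channel, 200 Hz sEMG
   (band-limited Gaussian interference pattern, envelope-modulated,
   seeded) is rectified, low-pass filtered and normalized to
   `α(t) ∈ [0,1]`, then mapped to neural activation
   `r = (e^{γα} − 1)/(e^{γ} − 1)`.
2. **Activation → force.** The Huxley cross-bridge bond-distribution
   PDE `∂p/∂t − v ∂p/∂x = r f (1−p) − g p` is discretized by Chebyshev
   collocation and reduced by balanced truncation to a 3-state model
   `ȧ = (A0 + v A1) a + B r`, `F = C a`, with the shortening velocity
   closed through the Hill relation
   `v = vb (F0 + Fa)/(Fa + F) − vb`.
3. **Force → stiffness.** Muscle stiffness is the windowed force
   change per unit shortening, `K = ΔF / ΔX` with
   `ΔX = vb ∫ (F0 − F)/(Fa + F) dt`, normalized as `Ka = K / Kmax`.
4. **Stiffness → controller stiffness.** A 5×5 fuzzy rule base over
   triangular partitions of `(Ka, ΔKa)` yields the controller
   stiffness `K̃d` (monotone by construction).
5. **Impedance control.** A five-link, one-actuator linkage finger
   (`M θ̈ + C θ̇² + G = τ − JᵀF − f`) is driven by
   `u = M Γ1 + JᵀF + f̃ + C θ̇² + G`,
   `Γ1 = θ̈d − Md⁻¹[Bd ė + Kd e + (F − Fd)]`, against linear-spring
   objects, while the Lyapunov pair
   `V = ė²/2 + (Kd + K_eff) Md⁻¹ e²/2`, `V̇ = −Bd Md⁻¹ ė²` is logged
   to certify stability.

See `vignettes/compliant-grasp-methods.Rmd` for the models, the
numerical choices and their rationale.

## Worked example: four objects, soft to hard

```r
library(semgrasp)
demo <- demo_objects(seed = 1)
print(demo)
```

```
Four-object compliant grasp comparison
                  label contact_ms settling_ms final_force_N max_angle_deg
 single-layer paper cup       1266         247         1.140         33.89
 double-layer paper cup       1262         181         1.828         32.94
            milk carton       1260          89         2.106         30.88
            plastic cup       1259          67         3.152         30.39
 Ka_terminal Kd_tilde_terminal
      0.0100              8.33
      0.0243             14.60
      0.0457             63.44
      0.0771             91.67
```

Reading the table: the four scenarios emulate a wearer gripping a
single-layer paper cup, a double-layer paper cup, a milk carton and a
plastic cup — progressively higher and faster-rising muscle effort
against progressively stiffer objects. Down the rows, the peak
normalized muscle stiffness `Ka` rises (1.0% → 7.7% of the calibrated
maximum), the fuzzy-scheduled controller stiffness `K̃d` rises
(8.3 → 91.7 on its 0–100 scale), the force finally applied by the
finger rises (1.14 N → 3.15 N), and the settling time — contact to
the force staying within ±2% of its final value — falls
(247 ms → 67 ms). That is the compliant-grasp signature: gentle and
slow on fragile objects, firm and fast on robust ones, decoded
entirely from the (synthetic) sEMG.

Single pieces of the chain are just as accessible:

```r
act  <- activation(0.5, gamma = 2)        # 1/(e+1) ≈ 0.26894
hill <- hill_parameters(F0 = 10, Fa = 4, vb = 0.1)
shortening_velocity(6, hill)              # 0.04 lengths/s
infer_kd(0.05, 0.03)                      # scheduled stiffness on [0,100]
```

A command-line front end over the same functions lives in
`inst/cli/semgrasp-cli.R` (`gen-emg`, `estimate`, `grasp`, `demo`),
with example YAML inputs under `inst/extdata/`.

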