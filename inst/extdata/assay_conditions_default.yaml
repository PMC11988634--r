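# Final in-well conditions for the 200 uL Ellman microplate format.
# All keys are optional; omitted keys fall back to the package defaults.
substrateConc: 0.5        # mM acetylthiocholine, final
chromogenConc: 0.25       # mM DTNB, final
enzymeActivity: 0.001875  # U/mL, final
finalVolume: 200          # uL
pathLength: 0.58          # cm
extinctionCoef: 13600     # 1/(M cm), TNB at 405 nm
Km: 0.1                   # mM
duration: 300             # s
readInterval: 15          # s
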