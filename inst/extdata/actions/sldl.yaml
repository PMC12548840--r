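# Stiff-legged deadlift (SLDL): flexion range 0-90 deg, first peak torque 893 N.m,
# first peak earlier than the conventional lift
action_id: SLDL
flexion_start_deg: 0
flexion_end_deg: 90
first_peak_torque_Nm: 893
second_peak_torque_Nm: 759.05
peak_time_fractions: [0.26, 0.74]
trial_duration_s: 2
barbell_mass_kg: 120
noise_sd_mm: 0.5
seed: 0
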