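code,description
SR1,Being shocked
SR2,Being conflagrated
SR3,Being trapped
SR4,Fall from height
SR5,Slip on the floor
SR6,Being struck against objects
SR7,Being struck by falling objects
SR8,Thermal burn
SR9,Cut-in
SR10,Drowning
SR11,Spinal disc injury
SR12,Wrist damages
SR13,Damages to the tendons
SR14,Stenosing tenosynovitis
SR15,Neck stiffness
SR16,White Finger Disease
SR17,Mental perturbation
SR18,Fatigue
SR19,Thoracic Outlet Syndrome
SR20,Heat stroke
SR21,Dengi fever
SR22,Hyperthermia
SR23,Chemical rash
SR24,Chemical burns
SR25,Prepatellar bursitis
SR26,Chemical eye burns
SR27,Acute inhalation injury
SR28,Arrhythmia
SR29,Being choked
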