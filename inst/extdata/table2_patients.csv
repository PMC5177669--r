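# Five surgically treated basilar apex aneurysm patients: published
# per-patient measurements (all distances in mm).
# Transcription notes (several printed cells run digits together; they were
# resolved against the published case-series narrative):
#  - Heights of point A span 3-12 mm across the five patients, per the
#    narrative's stated range; this fixes the height_A column.
#  - Patient 3: the narrative states C-Z and C-L distances of 3.6 and
#    3.1 cm, fixing cz_mm = 36 and cl_mm = 31; the remaining digits give
#    height_A 9, height_B 12, width_B 9.
#  - Patient 5: the representative case report gives point C 2.3 cm above
#    the zygomatic arch and 2.9 cm from the lateral canthus, consistent
#    with cz_mm = 23.3 and cl_mm = 28.7.
#  - Patients 1-2 (no orbitozygomatic approach) have C-Z and C-L > 40 mm;
#    patients 4-5 (orbitozygomatic approach) have both < 30 mm, matching
#    the narrative. Patient 1's cz_mm/cl_mm (87, 85.1) are the least
#    certain transcription (run-together digits); they satisfy the stated
#    ">5 cm" condition but carry lower confidence than the other rows.
#  - The narrative sentence calling patient 5 the "highest" apex conflicts
#    with patient 4's height_A = 12 under this reading; the stated range
#    (3-12 mm) was taken as authoritative.
patient,age,sex,location,size_mm,ruptured,height_A_mm,height_B_mm,width_B_mm,cz_mm,cl_mm,approach
1,58,M,basilar_tip,7,ruptured,3,6,16.8,87,85.1,clipping_right_pterional
2,77,F,ba_sca,5,ruptured,6,9,13.9,57,47.9,clipping_left_pterional_anterior_clinoidectomy
3,74,F,ba_sca,5,unruptured,9,12,9,36,31,coating_left_pterional
4,79,F,basilar_tip,3,ruptured,12,6,16.8,15,29.5,clipping_right_oza
5,36,F,ba_sca,7,unruptured,4,2.8,18,23.3,28.7,clipping_right_oza
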