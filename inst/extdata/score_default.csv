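"voice","piece","event_index","midi_pitch","onset_beats","duration_beats"
"soprano","Agnus I",1,70,0,0.5
"soprano","Agnus I",2,72,0.5,1
"soprano","Agnus I",3,71,1.5,1
"soprano","Agnus I",4,73,2.5,1
"soprano","Agnus I",5,71,3.5,1
"soprano","Agnus I",6,69,4.5,0.5
"soprano","Agnus I",7,71,5,2
"soprano","Agnus I",8,72,7,0.5
"altus","Agnus I",1,64,0,1
"altus","Agnus I",2,66,1,1
"altus","Agnus I",3,68,2,1
"altus","Agnus I",4,66,3,0.5
"altus","Agnus I",5,64,3.5,1
"altus","Agnus I",6,65,4.5,1
"altus","Agnus I",7,67,5.5,0.5
"altus","Agnus I",8,68,6,1
"tenor","Agnus I",1,58,0,1
"tenor","Agnus I",2,56,1,1
"tenor","Agnus I",3,57,2,2
"tenor","Agnus I",4,55,4,0.5
"tenor","Agnus I",5,53,4.5,1
"tenor","Agnus I",6,51,5.5,0.5
"tenor","Agnus I",7,52,6,2
"tenor","Agnus I",8,50,8,2
"bassus","Agnus I",1,50,0,1
"bassus","Agnus I",2,51,1,1
"bassus","Agnus I",3,52,2,1
"bassus","Agnus I",4,54,3,0.5
"bassus","Agnus I",5,53,3.5,1
"bassus","Agnus I",6,51,4.5,1
"bassus","Agnus I",7,53,5.5,1
"bassus","Agnus I",8,51,6.5,2
"soprano","Agnus II",1,70,0,0.5
"soprano","Agnus II",2,68,0.5,1
"soprano","Agnus II",3,69,1.5,2
"soprano","Agnus II",4,68,3.5,2
"soprano","Agnus II",5,69,5.5,0.5
"soprano","Agnus II",6,67,6,1
"soprano","Agnus II",7,65,7,2
"soprano","Agnus II",8,66,9,2
"bassus","Agnus II",1,50,0,0.5
"bassus","Agnus II",2,51,0.5,2
"bassus","Agnus II",3,49,2.5,0.5
"bassus","Agnus II",4,51,3,0.5
"bassus","Agnus II",5,53,3.5,1
"bassus","Agnus II",6,54,4.5,1
"bassus","Agnus II",7,56,5.5,1
"bassus","Agnus II",8,55,6.5,0.5
"soprano","Agnus III",1,70,0,1
"soprano","Agnus III",2,72,1,1
"soprano","Agnus III",3,74,2,1
"soprano","Agnus III",4,72,3,1
"soprano","Agnus III",5,70,4,1
"soprano","Agnus III",6,69,5,0.5
"soprano","Agnus III",7,70,5.5,1
"soprano","Agnus III",8,72,6.5,2
"altus","Agnus III",1,64,0,1
"altus","Agnus III",2,65,1,1
"altus","Agnus III",3,63,2,2
"altus","Agnus III",4,65,4,1
"altus","Agnus III",5,67,5,1
"altus","Agnus III",6,68,6,0.5
"altus","Agnus III",7,69,6.5,2
"altus","Agnus III",8,70,8.5,1
"tenor","Agnus III",1,58,0,1
"tenor","Agnus III",2,60,1,0.5
"tenor","Agnus III",3,61,1.5,0.5
"tenor","Agnus III",4,62,2,1
"tenor","Agnus III",5,61,3,1
"tenor","Agnus III",6,59,4,1
"tenor","Agnus III",7,60,5,0.5
"tenor","Agnus III",8,58,5.5,2
"bassus","Agnus III",1,50,0,0.5
"bassus","Agnus III",2,48,0.5,0.5
"bassus","Agnus III",3,47,1,1
"bassus","Agnus III",4,46,2,1
"bassus","Agnus III",5,45,3,2
"bassus","Agnus III",6,47,5,1
"bassus","Agnus III",7,48,6,2
"bassus","Agnus III",8,46,8,1
"soprano","Kyrie I",1,70,0,0.5
"soprano","Kyrie I",2,72,0.5,1
"soprano","Kyrie I",3,74,1.5,1
"soprano","Kyrie I",4,76,2.5,1
"soprano","Kyrie I",5,78,3.5,1
"soprano","Kyrie I",6,79,4.5,1
"soprano","Kyrie I",7,78,5.5,0.5
"soprano","Kyrie I",8,77,6,2
"altus","Kyrie I",1,64,0,2
"altus","Kyrie I",2,62,2,2
"altus","Kyrie I",3,60,4,1
"altus","Kyrie I",4,61,5,0.5
"altus","Kyrie I",5,60,5.5,1
"altus","Kyrie I",6,62,6.5,0.5
"altus","Kyrie I",7,61,7,1
"altus","Kyrie I",8,63,8,1
"tenor","Kyrie I",1,58,0,1
"tenor","Kyrie I",2,57,1,1
"tenor","Kyrie I",3,56,2,1
"tenor","Kyrie I",4,55,3,1
"tenor","Kyrie I",5,57,4,1
"tenor","Kyrie I",6,55,5,2
"tenor","Kyrie I",7,53,7,1
"tenor","Kyrie I",8,54,8,1
"bassus","Kyrie I",1,50,0,1
"bassus","Kyrie I",2,48,1,1
"bassus","Kyrie I",3,46,2,1
"bassus","Kyrie I",4,45,3,0.5
"bassus","Kyrie I",5,47,3.5,0.5
"bassus","Kyrie I",6,46,4,1
"bassus","Kyrie I",7,45,5,2
"bassus","Kyrie I",8,47,7,1
"soprano","Kyrie II",1,70,0,1
"soprano","Kyrie II",2,72,1,1
"soprano","Kyrie II",3,70,2,0.5
"soprano","Kyrie II",4,68,2.5,2
"soprano","Kyrie II",5,67,4.5,1
"soprano","Kyrie II",6,66,5.5,1
"soprano","Kyrie II",7,67,6.5,2
"soprano","Kyrie II",8,69,8.5,0.5
"altus","Kyrie II",1,64,0,1
"altus","Kyrie II",2,66,1,1
"altus","Kyrie II",3,68,2,0.5
"altus","Kyrie II",4,69,2.5,1
"altus","Kyrie II",5,68,3.5,1
"altus","Kyrie II",6,69,4.5,0.5
"altus","Kyrie II",7,70,5,2
"altus","Kyrie II",8,68,7,0.5
"tenor","Kyrie II",1,58,0,0.5
"tenor","Kyrie II",2,59,0.5,0.5
"tenor","Kyrie II",3,60,1,1
"tenor","Kyrie II",4,59,2,0.5
"tenor","Kyrie II",5,58,2.5,1
"tenor","Kyrie II",6,56,3.5,2
"tenor","Kyrie II",7,54,5.5,0.5
"tenor","Kyrie II",8,53,6,1
"bassus","Kyrie II",1,50,0,1
"bassus","Kyrie II",2,51,1,0.5
"bassus","Kyrie II",3,49,1.5,1
"bassus","Kyrie II",4,51,2.5,1
"bassus","Kyrie II",5,50,3.5,0.5
"bassus","Kyrie II",6,49,4,1
"bassus","Kyrie II",7,51,5,0.5
"bassus","Kyrie II",8,52,5.5,1
"soprano","Gloria",1,70,0,0.5
"soprano","Gloria",2,69,0.5,1
"soprano","Gloria",3,67,1.5,1
"soprano","Gloria",4,68,2.5,1
"soprano","Gloria",5,67,3.5,1
"soprano","Gloria",6,65,4.5,0.5
"soprano","Gloria",7,67,5,1
"soprano","Gloria",8,69,6,1
"altus","Gloria",1,64,0,0.5
"altus","Gloria",2,66,0.5,2
"altus","Gloria",3,67,2.5,2
"altus","Gloria",4,69,4.5,1
"altus","Gloria",5,71,5.5,1
"altus","Gloria",6,69,6.5,1
"altus","Gloria",7,67,7.5,2
"altus","Gloria",8,66,9.5,0.5
"tenor","Gloria",1,58,0,1
"tenor","Gloria",2,60,1,0.5
"tenor","Gloria",3,58,1.5,1
"tenor","Gloria",4,59,2.5,1
"tenor","Gloria",5,58,3.5,1
"tenor","Gloria",6,59,4.5,1
"tenor","Gloria",7,57,5.5,1
"tenor","Gloria",8,59,6.5,1
"bassus","Gloria",1,50,0,0.5
"bassus","Gloria",2,51,0.5,2
"bassus","Gloria",3,53,2.5,1
"bassus","Gloria",4,55,3.5,0.5
"bassus","Gloria",5,53,4,1
"bassus","Gloria",6,55,5,0.5
"bassus","Gloria",7,54,5.5,1
"bassus","Gloria",8,52,6.5,1
"soprano","Virgo prudentissima",1,70,0,0.5
"soprano","Virgo prudentissima",2,68,0.5,1
"soprano","Virgo prudentissima",3,66,1.5,1
"soprano","Virgo prudentissima",4,64,2.5,1
"soprano","Virgo prudentissima",5,62,3.5,2
"soprano","Virgo prudentissima",6,64,5.5,0.5
"soprano","Virgo prudentissima",7,65,6,0.5
"soprano","Virgo prudentissima",8,64,6.5,1
"altus","Virgo prudentissima",1,64,0,0.5
"altus","Virgo prudentissima",2,63,0.5,1
"altus","Virgo prudentissima",3,62,1.5,1
"altus","Virgo prudentissima",4,64,2.5,1
"altus","Virgo prudentissima",5,65,3.5,1
"altus","Virgo prudentissima",6,66,4.5,1
"altus","Virgo prudentissima",7,65,5.5,2
"altus","Virgo prudentissima",8,67,7.5,1
"tenor","Virgo prudentissima",1,58,0,2
"tenor","Virgo prudentissima",2,57,2,1
"tenor","Virgo prudentissima",3,58,3,1
"tenor","Virgo prudentissima",4,59,4,1
"tenor","Virgo prudentissima",5,57,5,1
"tenor","Virgo prudentissima",6,59,6,0.5
"tenor","Virgo prudentissima",7,57,6.5,2
"tenor","Virgo prudentissima",8,56,8.5,2
"bassus","Virgo prudentissima",1,50,0,1
"bassus","Virgo prudentissima",2,51,1,2
"bassus","Virgo prudentissima",3,52,3,0.5
"bassus","Virgo prudentissima",4,50,3.5,2
"bassus","Virgo prudentissima",5,51,5.5,2
"bassus","Virgo prudentissima",6,53,7.5,0.5
"bassus","Virgo prudentissima",7,51,8,2
"bassus","Virgo prudentissima",8,52,10,1
"soprano","D'ung aultre amer",1,70,0,1
"soprano","D'ung aultre amer",2,68,1,1
"soprano","D'ung aultre amer",3,69,2,1
"soprano","D'ung aultre amer",4,68,3,1
"soprano","D'ung aultre amer",5,70,4,1
"soprano","D'ung aultre amer",6,72,5,2
"soprano","D'ung aultre amer",7,70,7,0.5
"soprano","D'ung aultre amer",8,69,7.5,0.5
"altus","D'ung aultre amer",1,64,0,1
"altus","D'ung aultre amer",2,62,1,1
"altus","D'ung aultre amer",3,64,2,2
"altus","D'ung aultre amer",4,62,4,2
"altus","D'ung aultre amer",5,61,6,1
"altus","D'ung aultre amer",6,59,7,1
"altus","D'ung aultre amer",7,61,8,0.5
"altus","D'ung aultre amer",8,60,8.5,2
"tenor","D'ung aultre amer",1,58,0,1
"tenor","D'ung aultre amer",2,60,1,2
"tenor","D'ung aultre amer",3,58,3,1
"tenor","D'ung aultre amer",4,59,4,0.5
"tenor","D'ung aultre amer",5,61,4.5,0.5
"tenor","D'ung aultre amer",6,62,5,1
"tenor","D'ung aultre amer",7,60,6,0.5
"tenor","D'ung aultre amer",8,62,6.5,1
"bassus","D'ung aultre amer",1,50,0,0.5
"bassus","D'ung aultre amer",2,48,0.5,1
"bassus","D'ung aultre amer",3,50,1.5,2
"bassus","D'ung aultre amer",4,49,3.5,2
"bassus","D'ung aultre amer",5,47,5.5,1
"bassus","D'ung aultre amer",6,48,6.5,2
"bassus","D'ung aultre amer",7,46,8.5,1
"bassus","D'ung aultre amer",8,45,9.5,1
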