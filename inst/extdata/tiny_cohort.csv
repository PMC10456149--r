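patient_id,cohort,gender,height_cm,age_years,admission_weight_kg,region,pf_entry,pf_end,pf_lowest,pplat_entry,pplat_end,pplat_highest,cxr_quadrants_entry,cxr_quadrants_end,cxr_quadrants_highest,sofa_entry,sofa_end,sofa_highest,doc_entry,doc_end,vt_d1,vt_d2,vt_d3,mode_d1,mode_d2,mode_d3
pt00001,ARDS,male,174,48,78,South America,283.8,300,252.4,13.5,13.4,14.2,3,2,3,3,4,5,FALSE,FALSE,578.2,573.1,576.8,PCV,PSV,PSV
pt00002,ARDS,male,179.7,24,85.7,Europe,141.5,156.1,78,25.2,23.8,,3,3,3,9,8,,FALSE,FALSE,441.9,462.7,473.9,PCV,PCV,PCV
pt00003,ARDS,male,164.9,46,85.8,Europe,245.1,300,239.5,12.4,13.3,14.8,1,0,1,6,6,7,FALSE,FALSE,344.5,337.5,345.2,PSV,VAC,PCV
pt00004,ARDS,male,181.9,52,85.8,South America,186.2,206.1,176.6,25.1,24.8,25.9,2,2,2,9,9,10,TRUE,TRUE,515.1,513.5,519.4,PCV,SIMV,PCV
pt00005,ARDS,female,165.9,87,61.4,Europe,187,186.4,148.5,20.3,19.6,21.5,1,2,2,9,8,9,FALSE,FALSE,364.8,372.2,389.3,PSV,PCV,PCV
pt00006,ARDS,male,180.4,66,89.7,Europe,214.6,200.9,192.4,21.4,19,22.4,2,3,3,5,4,5,FALSE,FALSE,529.3,524.7,526.4,SIMV,PSV,PCV
pt00007,ARDS,male,172,55,98,Africa,181,168.3,141.9,22.9,21.9,23.8,0,0,1,8,8,9,FALSE,FALSE,530.8,531.3,538.2,VAC,SIMV,SIMV
pt00008,ARDS,female,161.5,68,61.1,Asia,292.2,292.7,258.6,,13.5,17.2,0,0,0,2,3,4,FALSE,FALSE,338.3,331.6,324.8,SIMV,PSV,SIMV
pt00009,ARDS,female,170,86,61.8,Europe,300,300,252.7,22.2,23.1,23.3,1,1,1,5,6,6,FALSE,FALSE,431.1,430.3,418.1,PCV,PCV,PSV
pt00010,ARDS,male,180,81,84.9,Europe,223.3,264.6,211.2,24.3,24.8,25,1,2,2,,4,,TRUE,TRUE,457.2,440,457.8,PSV,VAC,SIMV
pt00011,ARDS,male,176.7,56,77.8,Europe,63.9,124.3,55.3,27.8,,,2,2,3,11,12,12,FALSE,FALSE,443.1,421,430.9,PSV,PSV,PSV
pt00012,ARDS,male,160.4,55,81,Europe,260.8,280.6,196.1,20.8,20.1,20.9,3,3,3,4,5,6,FALSE,FALSE,527,517,535.1,SIMV,PSV,SIMV
pt00013,ARDS,male,177.8,75,76,North America,300,300,277.7,16.7,,19,1,0,1,3,3,4,FALSE,FALSE,547.8,539.4,541.2,VAC,PSV,PCV
pt00014,ARDS,male,173.1,83,73.6,Europe,215.8,221.6,189.3,14.9,13.5,16.8,1,0,1,8,8,8,FALSE,FALSE,549.7,520.5,525,PCV,SIMV,SIMV
pt00015,ARDS,female,175.8,45,59.1,Asia,193.2,205.1,163.3,,21.9,22.6,3,4,4,8,,9,FALSE,FALSE,526.8,525.5,543.6,VAC,VAC,VAC
pt00016,ARDS,male,166.3,57,60.9,Europe,240.2,217.1,175,21.8,,22.3,1,2,2,6,5,6,FALSE,FALSE,319.7,320.2,328.2,VAC,PSV,PCV
pt00017,ARDS,female,164.7,54,62.8,North America,154.6,207.1,133.6,18.5,19.9,21,1,2,2,6,7,7,TRUE,TRUE,361.7,361.7,375.5,SIMV,SIMV,PSV
pt00018,ARDS,male,175.4,41,83.3,Africa,297.3,278,225.6,18.3,20.3,21.5,2,1,2,6,5,6,FALSE,FALSE,554.2,,543.5,PSV,PCV,PCV
pt00019,ARDS,female,166.6,36,74.9,North America,164.2,211.1,123.6,19.7,,21,2,3,3,7,7,8,TRUE,TRUE,356,358.8,381.8,PSV,PSV,VAC
pt00020,ARDS,female,151,77,55.8,North America,233,212.6,193,,,24.6,2,3,3,7,,,TRUE,TRUE,243.1,266.6,262.5,SIMV,VAC,PCV
pt00021,ARDS,female,165.2,58,67,Asia,79.1,100.1,54.5,25.7,23.8,26,2,3,3,10,11,11,FALSE,FALSE,375.3,379.4,371.4,PCV,VAC,VAC
pt00022,ARDS,male,165,67,67.2,Asia,104.4,59.3,56.6,29.6,27.4,29.6,4,3,4,11,,12,TRUE,TRUE,407.5,394.5,398.3,VAC,SIMV,PSV
pt00023,ARDS,female,166.2,40,62.2,North America,154.9,171.4,128.9,22.3,23,25,4,4,4,10,,11,TRUE,TRUE,350.6,362.4,362.8,PCV,SIMV,SIMV
pt00024,ARDS,female,153.8,22,65.4,Asia,89.4,60.5,57.3,21.5,19.8,,3,2,3,9,8,9,FALSE,FALSE,357.8,358.9,380.2,VAC,SIMV,SIMV
pt00025,ARDS,male,177.8,47,76.9,North America,106.7,104.5,86.1,24.3,25.7,25.7,4,4,4,8,7,8,TRUE,TRUE,416.9,420.6,445.2,PCV,VAC,SIMV
pt00026,ARDS,female,153.6,78,49.5,Asia,200.1,191.7,157.7,25.8,,26,3,3,3,,7,9,TRUE,TRUE,314.5,352.5,314.8,VAC,VAC,SIMV
pt00027,ARDS,female,160.3,48,60.4,North America,300,300,257.9,20,,23.1,1,1,1,8,8,8,FALSE,FALSE,441.8,448.5,447.2,VAC,VAC,SIMV
pt00028,ARDS,male,176.5,32,72.4,Europe,175.3,219.3,124.3,18.2,19.4,19.6,3,4,4,10,11,11,FALSE,FALSE,546,553.3,,PCV,PSV,PSV
pt00029,ARDS,male,172.7,84,91.4,Europe,283.3,300,266.3,14.7,15.6,15.7,1,2,2,8,7,8,FALSE,FALSE,472.1,445.8,450.3,VAC,VAC,VAC
pt00030,ARDS,male,179.8,73,,Europe,300,,267.2,14.8,13.6,17.1,0,1,1,2,3,4,FALSE,FALSE,546.1,559.9,546.4,PSV,SIMV,PCV
pt00031,ARDS,male,177.4,84,79,Asia,167.7,205.5,161.5,18.8,19.3,19.8,0,0,1,7,8,9,FALSE,FALSE,514.9,499.6,495.7,VAC,SIMV,PCV
pt00032,ARDS,male,178.4,62,110,Europe,106.5,89.1,83.8,22,22.5,24.3,2,2,3,5,,6,FALSE,FALSE,453.1,452.4,463.1,PCV,VAC,PSV
pt00033,ARDS,male,185.1,90,87.3,North America,199.9,255.8,182.5,20,20.9,,2,2,3,8,,8,FALSE,FALSE,443.6,442.9,462.2,PSV,VAC,PSV
pt00034,ARDS,female,162.3,68,44.3,South America,247.7,215,192.2,23.7,23.4,,3,4,4,7,5,7,FALSE,FALSE,343.9,345.2,364.8,PCV,PSV,VAC
pt00035,ARDS,male,175.8,71,65.9,Europe,225,272.8,199,18.7,,19.3,3,3,3,6,6,8,TRUE,TRUE,414.8,418.9,,PSV,PSV,PSV
pt00036,ARDS,male,176.2,45,84.8,Europe,217.3,276.5,172.3,16,17.8,18.5,2,,3,9,10,10,FALSE,TRUE,406.1,414.9,,PCV,SIMV,VAC
pt00037,ARDS,male,194.8,78,,Europe,127.2,140.5,72.6,18.5,19.2,,2,3,3,8,9,9,FALSE,FALSE,468.6,469.5,483.7,VAC,VAC,VAC
pt00038,ARDS,male,174.4,32,90.8,Asia,197,204.1,162.7,24.4,20.5,24.4,1,1,1,,5,6,FALSE,FALSE,556.8,580.1,573.4,PCV,PSV,SIMV
pt00039,ARDS,male,175.6,36,92.8,Europe,121.3,96.5,74.2,20.2,,,3,3,3,9,7,9,TRUE,TRUE,357.6,357.2,361.7,SIMV,SIMV,VAC
pt00040,ARDS,female,172.6,75,69,Oceania,171.9,154.8,94.7,24.6,,25.3,2,2,2,10,10,11,FALSE,FALSE,387,382,408.2,PCV,PCV,VAC
pt00041,control,male,181.3,51,92.7,Europe,278,,255.3,18.3,18,18.6,1,1,1,,5,6,FALSE,FALSE,565.6,586.2,560.2,PSV,PSV,SIMV
pt00042,control,female,161.7,29,62.4,North America,227.4,192.6,151.3,17.6,,17.7,2,2,2,6,7,8,FALSE,FALSE,466.1,458.7,456.6,PCV,VAC,PCV
pt00043,control,female,175.1,84,48.9,Oceania,281.4,,275.5,9.3,10.7,11.4,0,1,1,6,,6,FALSE,FALSE,552.7,562.6,570.5,PCV,VAC,PCV
pt00044,control,female,164.4,79,70.2,Europe,277,300,264.5,18.8,,19.4,1,1,1,3,2,4,FALSE,FALSE,494.4,497.7,,PSV,PCV,PSV
pt00045,control,male,168.8,43,75.8,Europe,300,300,297.1,15,14.6,18.2,1,1,1,4,5,5,TRUE,TRUE,381.9,369.2,,VAC,VAC,VAC
pt00046,control,female,156.3,60,,North America,144.3,134.2,118.4,21.2,21.6,23,2,2,2,,11,11,FALSE,FALSE,486.2,472.3,470.6,PCV,SIMV,PSV
pt00047,control,male,171.4,22,108.1,Europe,294.2,300,257.9,19.9,17.2,20.7,1,2,2,7,6,8,FALSE,FALSE,523.7,527.9,521.4,PSV,PCV,PSV
pt00048,control,female,153.4,25,57.6,Asia,241.1,276.8,237.2,17.5,18.2,,2,2,2,3,2,3,FALSE,FALSE,454.3,432.2,430.8,PCV,PCV,PCV
pt00049,control,female,162.1,28,57.7,North America,242.2,234,213.6,12.1,11.1,,2,2,2,4,,5,FALSE,FALSE,524.3,513.3,,PSV,PSV,PSV
pt00050,control,male,168.3,29,53.7,Asia,186.2,184.9,153.8,24,22.8,24,4,,4,9,7,9,FALSE,FALSE,520.6,512.3,513,PCV,SIMV,PCV
pt00051,control,male,177.7,59,92.8,Asia,253.6,244,200.1,18,,18.7,1,0,1,7,7,7,FALSE,FALSE,515.2,530.4,545.8,PCV,PCV,SIMV
pt00052,control,female,156.7,20,57,North America,271.2,255.8,238.1,,18.8,18.9,2,,2,3,2,4,FALSE,FALSE,451,452.3,460.1,PCV,SIMV,PSV
pt00053,control,male,170.1,61,56.1,Europe,181.2,,172.5,16.7,17.1,17.6,2,1,2,4,4,,FALSE,FALSE,589.4,583.2,565.1,VAC,SIMV,VAC
pt00054,control,female,164.8,22,55.2,North America,175.5,198.3,156.4,25,26.5,26.9,2,2,3,6,7,7,FALSE,FALSE,496.6,493.2,516.8,VAC,PSV,PCV
pt00055,control,male,178.6,30,85.1,Europe,264.7,296.1,240.4,17.2,20.2,21.1,1,,2,6,7,7,FALSE,FALSE,515.6,500.6,495.8,PCV,SIMV,SIMV
pt00056,control,female,157.1,87,81.5,Africa,181.8,233.5,162.2,21.9,20.2,22.2,3,4,4,4,3,5,FALSE,FALSE,426.2,434.8,442.7,VAC,PCV,PSV
pt00057,control,male,171,83,86,Europe,300,300,297.9,13.8,16.1,,0,,0,7,5,7,FALSE,FALSE,499.1,495.3,504.6,PCV,PCV,VAC
pt00058,control,female,156.2,23,68.7,Europe,300,300,269.6,,,21,2,1,2,4,5,6,FALSE,FALSE,403.2,398.7,408,PSV,VAC,PCV
pt00059,control,female,153.8,25,52.6,North America,195.5,238.7,150.7,21.2,18.6,21.7,3,3,3,4,5,6,FALSE,FALSE,409.9,422.5,434.3,PCV,VAC,VAC
pt00060,control,male,184,75,89.2,South America,244.7,274.1,194.5,17.2,17.6,17.6,2,2,2,6,7,7,FALSE,FALSE,497.1,510.4,502.3,PCV,VAC,PCV
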